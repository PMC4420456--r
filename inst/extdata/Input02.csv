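1,R,Pierce,133183594
2,M,Kramer,135370878
3,K,Battle,141274186
4,K,Mcclain,148965694
8,L,MUELLER,184498846
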
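1,Risa,Pierce,133183594,09261990,M,1524,Vesta,0676221410
2,Maile,Kramer,135370878,07261991,F,1526,Lenna,0957261480
3,Kimberly,Battle,141274186,04071982,F,1527,Jacki,0144591609
4,Kamal,Mcclain,148965694,10091991,M,70000,Luisa,0278635088
5,Yvonne,Vaughan,153614228,02061992,F,70003,Basil,0368901550
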
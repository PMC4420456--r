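1,RISA,PIERCE,09261990,M,001524,VESTA,0676221410
2,MAILE,KRAMER,07261991,F,001526,LENNA,0957261480
3,KIMBERLY,BATTLE,04071982,F,001527,JACKI,0144591609
5,YVONNE,VAUGHAN,02061992,F,070003,BASIL,0368901550
8,KELSIE,MUELLER,01131992,M,070020,JAKE,7243583370
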
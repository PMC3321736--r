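id,day,futime,status,age,pro,bili
5,0,1505,1,38.11,10.9,3.4
5,199,1505,1,38.65,10.7,1.9
5,391,1505,1,39.18,10.5,2.5
5,769,1505,1,40.21,11.4,5.7
5,1098,1505,1,41.11,11.3,5.2
5,1455,1505,1,42.09,13.9,19.0
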
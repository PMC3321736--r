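id,day,futime,status,age,pro,bili
9,0,2400,2,42.54,11.0,3.2
9,184,2400,2,43.04,12.5,7.0
9,361,2400,2,43.53,11.2,4.2
9,723,2400,2,44.52,14.1,13.5
9,1027,2400,2,45.35,11.5,12.0
9,1396,2400,2,46.36,11.5,16.2
9,2278,2400,2,48.78,13.0,14.8
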
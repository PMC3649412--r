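session,M0,M1,M2,M3,M4,M5,M6
Session 2,100,100,100,100,80,100,80
Session 3,80,100,100,80,100,100,100
Session 4,100,80,100,80,100,80,100
Session 5,100,100,100,80,80,100,80
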
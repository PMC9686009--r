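hu,red
-1000,0
0,1.0
100,1.1
800,1.456
1500,1.8
3000,2.43
3600,3.73
4200,6.83
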
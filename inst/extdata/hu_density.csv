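hu,density_g_cm3
-1050,0.00121
-950,0.102
-120,0.950
-52,0.987
0,1.000
100,1.059
500,1.335
1000,1.609
1500,1.904
1640,4.506
2923,10.490
3095,7.310
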
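participant,chewer_group,sample,s0_mg,sf_mg,ks_e2_per_min
P2,fast,A,78.4,196.4,2.7
P2,fast,B,108.5,214.6,3.0
P2,fast,C,110.6,186.9,1.9
P14,fast,A,90.5,240.0,2.3
P14,fast,B,105.9,216.0,1.8
P14,fast,C,64.4,154.6,1.4
P16,fast,A,50.6,133.8,1.6
P16,fast,B,112.5,209.5,1.4
P16,fast,C,103.4,200.9,1.8
P12,slow,A,107.3,216.0,1.5
P12,slow,B,156.2,289.2,1.0
P12,slow,C,168.0,303.8,1.8
P19,slow,A,152.3,324.8,2.3
P19,slow,B,145.1,306.4,2.1
P19,slow,C,128.6,306.5,2.1
P21,slow,A,102.6,340.7,1.9
P21,slow,B,121.6,343.0,2.5
P21,slow,C,152.9,338.8,1.6
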
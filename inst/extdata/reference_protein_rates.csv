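participant,chewer_group,sample,kp_e2_per_min
P2,fast,A,6.2
P2,fast,B,10.4
P2,fast,C,4.1
P4,fast,A,5.5
P4,fast,B,9.2
P4,fast,C,4.3
P16,fast,A,4.7
P16,fast,B,8.4
P16,fast,C,5.4
P12,slow,A,10.2
P12,slow,B,16.1
P12,slow,C,11.5
P19,slow,A,6.7
P19,slow,B,10.5
P19,slow,C,9.6
P21,slow,A,7.7
P21,slow,B,7.5
P21,slow,C,9.0
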
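participant,chewer_group,sample,rds_pct,sds_pct,rs_pct
P2,fast,A,32.8,19.5,47.8
P2,fast,B,42.91,17.6,39.52
P2,fast,C,38.6,18.6,42.9
P14,fast,A,37.7,21.8,40.5
P14,fast,B,37.0,19.3,43.71
P14,fast,C,27.7,10.9,61.32
P16,fast,A,20.81,13.6,65.6
P16,fast,B,29.6,18.6,51.8
P16,fast,C,34.0,13.2,52.8
P12,slow,A,39.0,26.2,33.4
P12,slow,B,47.8,24.5,27.7
P12,slow,C,57.4,19.6,23.0
P19,slow,A,56.4,26.4,17.2
P19,slow,B,69.1,19.1,13.6
P19,slow,C,51.6,24.3,24.2
P21,slow,A,46.2,29.9,24.0
P21,slow,B,54.9,27.4,17.7
P21,slow,C,61.8,28.3,11.7
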
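sample,class_scope,x50_mm2,b
A,all,5.0,1.63
B,all,5.2,1.60
C,all,5.4,1.53
A,white,3.5,1.9
B,white,3.5,1.9
C,white,3.7,1.8
A,black,6.7,1.7
B,black,7.1,1.7
C,black,7.6,1.58
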
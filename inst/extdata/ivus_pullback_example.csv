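frame,position,max_d,min_d,avg_d,area
1,0.0167,4.26,3.98,4.13,13.2
2,0.0335,4.24,3.98,4.12,13.2
3,0.0503,4.24,3.98,4.12,13.2
4,0.0671,4.24,3.98,4.12,13.2
5,0.0838,4.24,3.98,4.12,13.2
6,0.100,4.23,3.98,4.11,13.1
7,0.117,4.23,3.98,4.11,13.1
8,0.134,4.23,3.98,4.11,13.1
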
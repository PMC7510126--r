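subject,gm_f,gm_att,gm_t1,cp_f,cp_att,cp_t1
1,42.55,1.37,1.93,39.73,1.35,2.45
2,63.70,1.16,1.83,27.40,0.83,2.85
3,61.30,1.12,1.83,58.13,1.27,1.94
4,56.33,1.29,1.77,46.03,1.10,2.32
5,54.65,1.35,1.71,38.47,1.43,1.90
6,47.04,1.45,2.02,40.24,1.45,2.42
7,50.63,1.41,1.85,26.40,1.23,2.42
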
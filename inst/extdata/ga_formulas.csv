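formula_id,measure,c0,c1,c2,c3,min_mm,max_mm
hadlock1984_bpd,bpd,9.54,1.482,0.1676,0,15,100
hadlock1984_hc,hc,8.96,0.540,0,0.0003,80,360
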
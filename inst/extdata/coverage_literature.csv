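dopc_dppc_ratio,method,coverage_pct,margin_pct
1:1,histogram,29,3
1:1,particle,25,3
3:7,histogram,55.6,0.6
3:7,particle,53,4
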
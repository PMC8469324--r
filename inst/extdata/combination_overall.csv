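dose,effect_pct,n
34.00,62.80,6
17.00,50.60,6
8.51,48.70,6
4.27,43.51,6
2.12,33.48,6
1.06,30.41,6
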
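dose,effect_pct,n
3.16,14.78,6
10.00,38.77,6
31.62,46.85,6
100.00,56.02,6
316.22,62.43,6
562.34,72.94,6
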
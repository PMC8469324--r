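dose,effect_pct,n
10.00,4.83,6
31.62,25.99,6
100.00,28.69,6
316.22,57.81,6
562.34,60.92,6
1000.00,80.22,6
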
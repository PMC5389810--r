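t,h
10,31.18
22,31.18
47,30.4275
72,30.3839
97,32.3329
122,32.4219
147,30.8689
172,31.5445
197,32.5955
222,32.1373
242,31.9685
250,29.5804
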
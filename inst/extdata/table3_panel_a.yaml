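# Power-grid configuration: hypothesis "pair (1,2) differs", null OR 3,
# homogeneous margins on a 5-category scale.
I: 5
hypothesis: beta12
null_or: 3
ks: [1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 12, 14, 16]
ns: [50, 100, 150, 200, 250]
margins: [0.2, 0.2, 0.2, 0.2, 0.2]
alpha: 0.05
nsim: 2000
seed: 20110517
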
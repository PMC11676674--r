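conditions: [NC, MMC-0.025]
replicates: 2
fields_per_replicate: 3
master_seed: 42
shape: [1800, 1800]
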
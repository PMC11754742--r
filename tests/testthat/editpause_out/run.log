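[20:49:56] editpause 1.0.0
[20:49:56] thresholds: fold_min=3 min_norm_reads=100 min_replicates=2
[20:49:56] scaffold 'toy': 4 ES; amplicon window ES1-ES4
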
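# Example cluster -> HSPC-group mapping for clusterFractions(). Cluster
# names are dataset-specific; this mapping mirrors the groups produced by
# defaultSimConfig(). Edit to match your own cluster annotation.
"HSC/MPP": "HSC/MPP"
"MEMB_early": "early_MEMB"
"MEMB_late": "late_MEMB"
"My_early": "early_My"
"My_late": "late_My"
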
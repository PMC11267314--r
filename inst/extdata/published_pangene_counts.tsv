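quantity	value
genes_clustered	639349
total_clusters	49770
core_clusters	23217
dispensable_clusters	26553
softcore_clusters	6278
shell_clusters	20249
cloud_clusters	26
core_pct	46.6
dispensable_pct	53.4
softcore_pct	12.6
shell_pct	40.7
cloud_pct	0.1
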
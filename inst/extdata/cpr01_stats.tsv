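stat	value
n_genes_annotated	28269
population_het_pct	6.4
mean_line_het_pct	4.3
median_line_het_pct	1.2
max_line_het_pct	30.7
generations	7
n_input_markers	1387
n_mapped_markers	1336
n_distorted_markers	468
genome_gc_pct	30.8
gene_density_per_Mb	66.2
n_markers_pseudochromosome	1073
n_markers_unplaced_scaffold	215
n_markers_no_hit	12
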
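min_read_len = 25
adapter_error_rate = 0.12
min_adapter_overlap = 8
quality_trim_threshold = 12
min_5prime_read_len = 133
mapq_min_call = 20
mapq_min_split = 15
mapq_min_rna = 20
cluster_merge_gap = 100
fulllength_pair_window = 7000
known_insertion_window = 200
primer_min_suffix = 8
primer_full_mismatches = 2
support_min_3p_reads = 3
expression_flank = 1000
expressed_fpkm_threshold = 0.05
diag_positions = 5927,5928,5929
lineage_error_rate = 0.1
lineage_min_overlap = 16
profile_bin = 50
preta_support_ratio = 10
transduction_window = 500
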
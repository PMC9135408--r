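# External data drop-in locations

All analyses in this package run on synthetic data with planted ground
truth; nothing here is required. Two optional directories enable the
recomputation checks that operate on the originating study's distributed
data (which cannot be redistributed with the package):

- `supplementary_rime/` — the study's RIME peptide tables converted to
  the `read_rime_table()` TSV dialect (`bait`, `condition`, `replicate`,
  `protein_id`, `peptide_seq`, `spectral_count`), as
  `table2_creb5_conditions.tsv`, `table3_three_baits.tsv`,
  `table4_l434p.tsv`.
- `accessions/` — deposited ChIP-seq peak sets as BED
  (`creb5_control_peaks.bed`, `creb5_enzalutamide_peaks.bed`).
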
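# Minimal pipeline configuration for the bundled eight-sequence toy
# library. Paths are relative to the working directory; thresholds are
# scaled to the toy's exaggerated divergences.
fasta: toy_barcodes.fasta
metadata: toy_metadata.tsv
out_dir: toy_run
seed: 1
model: K2P
qc:
  min_length: 40
  max_ambiguous_frac: 0.05
motu:
  abgd_P: 0.02
  abgd_X: 1.5
  tcs_limit: 0.95
  resl_seed_threshold: 0.08
  resl_refine_range: [0.02, 0.08]
ibd:
  min_n: 3
  min_span_km: 10
  n_perm: 99
  alpha: 0.05
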
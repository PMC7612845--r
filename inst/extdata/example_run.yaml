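# Example configuration for runPipeline(): a small fully synthetic run.
seed: 1
out_dir: "emhscope_run"
stages:
  simulate: true
  score: true
  composition: true
  expansion: true
  identity: true
  gsea: true
  lda: true
simulate:
  n_genes: 1500
  cells_per_tissue: 600
  donors: 2
score:
  n_bins: 25
  n_ctrl: 50
identity:
  pole_a: {tissue: "BM", cluster: "HSC/MPP"}
  pole_b: {tissue: "SPL", cluster: "HSC/MPP"}
  n_top: 50
  fdr_cut: 0.05
  lfc_cut: 0.2
gsea:
  n_perm: 200
lda:
  true_frequency: 0.002
  doses: [250, 500, 1000]
  n_per_dose: [6, 6, 6]
  conf_level: 0.95
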
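# Example run configuration for `pukg run-all`.
# Either give edge_table/node_table + disease_cuis for a real graph, or a
# `simulate` block to generate a synthetic one (disease ids then default
# to the generated disease nodes).
out_dir: results
simulate:
  n_genes: 3000
  n_terms: 200
  alpha_true: 0.3
  label_fraction: 0.625
  p_feature_pos: 0.3
  p_feature_neg: 0.05
n_iterations: 40
n_folds: 5
decision_threshold: 0.5
top_k: 15
seed: 42
roles:
  disease: Disease
  compound: Compound
  gene: Gene
  term: EFO
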
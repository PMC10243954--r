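# Example pipeline configuration: simulate every input and run all stages.
seed: 1
output_dir: netpharm_out
simulate: {}            # syntheticConfig() defaults; override fields here
screen:
  ob: 30
  caco2: 0.4
  dl: 0.18
  half_life: 3
  max_ro5_violations: 1
targets:
  min_probability: 0.8
  genecards_top_fraction: 0.5
network:
  min_confidence: 0.4
mcode:
  degree_cutoff: 2
  node_score_cutoff: 0.2
  k_core: 2
  haircut: true
  fluff: false
rwr:
  restart: 0.7
  top_k: 10
proximity:
  null_groups: 50
enrichment:
  p_cutoff: 0.005
cluster:
  n_clusters: 4
docking:
  temperature: 298.15
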
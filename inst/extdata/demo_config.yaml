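# Seeded demo pipeline configuration: a small two-chemical, two-sex study
# with one planted regulon effect, run entirely from simulated inputs.
seed: 17
output_dir: demo_out
simulate:
  n_genes: 40
  n_treated: 2
  n_control: 3
  mode: lognormal
  noise_sd: 0.3
  chemicals:
    - name: PFAS-A
      class: PFAS
      doses: [1, 10, 100]
    - name: PAH-B
      class: PAH
      doses: [1, 10, 100]
  regulons:
    n_tfs: 3
    targets_per_tf: [4, 8]
    overlap_prob: 0
  effects:
    - tf: TF01
      direction: up
      max_log2fc: 1.5
thresholds:
  up: 0.6
  down: -0.6
  q: 0.1
top_k_doses: 3
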
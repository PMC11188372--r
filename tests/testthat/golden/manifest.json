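{
  "config": {
    "seed": 17,
    "simulate": {
      "n_genes": 40,
      "n_treated": 2,
      "n_control": 3,
      "mode": "lognormal",
      "noise_sd": 0.3,
      "chemicals": [
        {
          "name": "PFAS-A",
          "class": "PFAS",
          "doses": [1, 10, 100]
        },
        {
          "name": "PAH-B",
          "class": "PAH",
          "doses": [1, 10, 100]
        }
      ],
      "regulons": {
        "n_tfs": 3,
        "targets_per_tf": [4, 8],
        "overlap_prob": 0
      },
      "effects": [
        {
          "tf": "TF01",
          "direction": "up",
          "max_log2fc": 1.5
        }
      ]
    },
    "thresholds": {
      "up": 0.6,
      "down": -0.6,
      "q": 0.1
    },
    "top_k_doses": 3
  },
  "seed": 17,
  "input_hashes": {
    "log2.tsv": "bcae9bce07f9cb95d64d7ba2c8142d84",
    "metadata.tsv": "1aa0641e29c3461fb8a4de737447a9cd",
    "qc.tsv": "2b42c17b88ed27b7cd33774b69ac3693",
    "regulons.tsv": "366d6924142b5c82d913374987a29579",
    "truth.tsv": "4faa4821cd8d77a2b89f41fe9abc6e60"
  },
  "stage_counts": {
    "samples_in": 36,
    "samples_retained": 36,
    "fc_rows": 480,
    "network_edges": 16,
    "profile_rows": 36,
    "call_rows": 40,
    "concordance_rows": 0,
    "heatmap_genes": 11
  },
  "warnings": []
}
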
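{"kind": "ssa_sweep", "mode": "shared",
 "doses": [0.0, 0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.8, 0.9, 1.0,
           1.1, 1.2, 1.3, 1.4, 1.5, 1.6, 1.7, 1.8, 1.9, 2.0],
 "reps": 10, "t_end": 5000, "seed": 1, "out_dir": "results/noise_sweep"}
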
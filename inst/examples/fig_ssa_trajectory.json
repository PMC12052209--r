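{"kind": "ssa_single", "mode": "shared", "params": {"I1": 1.0},
 "t_end": 5000, "dt": 0.1, "seed": 42, "branch": "gfp_low",
 "out_dir": "results/ssa_trajectory"}
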
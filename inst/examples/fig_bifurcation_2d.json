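{"kind": "bifurcation_2d", "mode": "shared",
 "p_x": {"name": "I1", "range": [0, 2]},
 "p_y": {"name": "inv_Jp2", "range": [0, 1]},
 "out_dir": "results/bifurcation_2d"}
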
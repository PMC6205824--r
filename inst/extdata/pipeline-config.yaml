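# Example pipeline configuration: the default operating point.
# Load with read_pipeline_config().
seed: 7
n_bootstrap: 1000
p_cut: 0.10
rpkm_min: 5
distance_cut: 0.5
r_min: 0.9
distortion_cut: 10
n_top: 1000
min_counts: 200
alpha: 0.05
tau_background: 10
f_primary: 0.20
f_sub: 0.05
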
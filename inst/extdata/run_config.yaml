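# Example pipeline configuration; omitted keys keep their defaults
# (see default_run_config()).
n_restarts: 25
window_s: 30
target_fs_hz: 25
trim_start_s: 7200
feature_set: [hf, p5, sh]
covariate: true
seed: 1
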
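# Example single-run scenario for `ifdsim run --config ...`
# Keys are sim_config() arguments. Note: booleans must be lowercase
# (true/false); the key `N` is always read literally.
N: 40
proportion_active: 0.5
activity_high: 0.8
activity_low: 0.2
scheduler: discrete
stopping: true_ifd
n_rows: 7
n_cols: 7
seed: 42
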
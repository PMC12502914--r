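Synthetic example data generated with the package's own simulator
(sim_config(mode = "multi_task", q = 2, p = 6, n_train = 25,
pi_theta = 0.3, pi_delta = 0, seed = 2026), values rounded to 4 decimals):
one shared 25 x 6 feature matrix and two gaussian targets, in the
delimited layout consumed by cmd_fit()/read_features()/read_target().
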
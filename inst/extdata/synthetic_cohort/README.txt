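Synthetic demonstration cohort (6 subjects: 3 HC, 3 SZ), generated by
brainbody::simulate_cohort(sim_config(n_hc = 3, n_sz = 3, seed = 11)) and
written with write_cohort_files(). All values are simulated; the
expected-pattern registry is a statistical stand-in, not meta-analytic
effect sizes.
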
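# Full study profile: 24,161 women, expected 680 incident cases
# (106 in-situ + 574 invasive), 1,000 virtual genotype datasets,
# 10-fold cross-validation, a-priori risk thresholds 1%-10%.
n_subjects: 24161
insitu_cases: 106
invasive_cases: 574
panel: default
n_replicates: 1000
k_folds: 10
thresholds: [0.010, 0.015, 0.020, 0.025, 0.030, 0.050, 0.100]
n_boot: 200
seed: 1
out_dir: brcarisk_run
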
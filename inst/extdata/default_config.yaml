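# Default configuration of the eye-selection-criteria study replica.
# All stochastic stages derive their seeds from the single top-level seed.
seed: 1
generator:
  n_patients: 42        # pituitary-macroadenoma patients
  n_control_pool: 65    # healthy-volunteer pool before 1:1 age matching
  missing_rate: 0.05    # MCAR cell deletion rate before imputation
cutoffs:
  AOz12: 15.5           # uV, pVEP P100 amplitude at 12 arcmin
  BiNS: 65              # um, bi-nasal GCC+IPL sector thickness
bootstrap_iterations: 10000
ssbd:
  n_subsamples: 1000
  subsample_fraction: 0.8
  alpha: 0.5
  cv_folds: 5
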
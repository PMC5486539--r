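# Minimal smoke-test run: 2 animals, one mast year, default thresholds.
seed: 7
scheme: of_year
detector_k: 5
detector_min_step: 0.3
generator:
  seed: 7
  n_females: 1
  n_males: 1
thresholds:
  torpor_cutoff: 32
  hyperthermia_cutoff: 40
  subcutaneous_offset: 2
  multiday_cutoff_h: 24
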
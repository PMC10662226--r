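# Default pipeline configuration. Every key is optional; omitted keys take
# the documented defaults (see ?validateConfig).
species: [tomato, barley, maize]
seed: 1
alpha: 0.05
generate: true
out_dir: leafphys_run
stages: [simulate, fit_aci, fit_npq, spectra, infer]
noise:
  aci_sd: 0.3
  npq_sd: 0.02
  spectra_sd: 0.01
constants:
  gammastar: 42.75
  Kc: 404.9
  Ko: 278.4
  O: 210
c4:
  ci_cutoff: 100
  Kp: 80
n_technical: 3
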
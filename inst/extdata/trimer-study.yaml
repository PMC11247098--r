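# Reference study configuration: photosystem-like trimer driven by
# entangled twins (sigma0 = 1 meV, tau0 = 25 fs, omega_+ = 0.3 eV).
aggregate:
  site_energies: [2.25, 2.1, 2.1]
  coupling_J: 0.03
bath:
  form: ohmic
  gamma0: 0.0013
  cutoff: 0.2
  temperature: 300
  pure_dephasing: 0.0
photon:
  kind: entangled
  omega_plus: 0.3
  omega_minus: 0.0
  sigma0: 0.001
  tau0: 25
  Ts: 0
  Ti: 0
grids:
  omega_minus: {from: -0.22, to: 0.22, by: 0.001}
  T_axis: {from: 0, to: 700, by: 35}
  time_step: 0.25
  time_max: 1000
seed: 1
output:
  prefix: qusrs
  format: tsv
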
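# Fully independent community at the study's scale: the type-I-error /
# variance-ratio calibration baseline. Balanced occupancy keeps the 2x2
# tables as far from zero margins as possible.
n_sites: 67
n_days: 365
start_date: "2022-06-01"
species:
  - {name: sp01, psi: 0.5, mu: 4, k: 1.0}
  - {name: sp02, psi: 0.5, mu: 4, k: 1.0}
  - {name: sp03, psi: 0.5, mu: 4, k: 1.0}
  - {name: sp04, psi: 0.5, mu: 4, k: 1.0}
  - {name: sp05, psi: 0.5, mu: 4, k: 1.0}
  - {name: sp06, psi: 0.5, mu: 4, k: 1.0}
  - {name: sp07, psi: 0.5, mu: 4, k: 1.0}
  - {name: sp08, psi: 0.5, mu: 4, k: 1.0}
  - {name: sp09, psi: 0.5, mu: 4, k: 1.0}
  - {name: sp10, psi: 0.5, mu: 4, k: 1.0}
  - {name: sp11, psi: 0.5, mu: 4, k: 1.0}
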
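# Larger site grid with one planted positive and one planted negative pair,
# used for association-recovery checks.
n_sites: 200
n_days: 365
start_date: "2022-06-01"
species:
  - {name: sp1, psi: 0.5, mu: 3, k: 1.0}
  - {name: sp2, psi: 0.5, mu: 3, k: 1.0}
  - {name: sp3, psi: 0.5, mu: 3, k: 1.0}
  - {name: sp4, psi: 0.5, mu: 3, k: 1.0}
  - {name: sp5, psi: 0.5, mu: 3, k: 1.0}
  - {name: sp6, psi: 0.5, mu: 3, k: 1.0}
associations:
  - {a: sp1, b: sp2, phi: 0.6}
  - {a: sp3, b: sp4, phi: -0.4}
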
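# 67-camera, one-year deployment with occupancies spanning ~7-60 sites,
# a bimodal crepuscular focal species (elephant), one strong positive pair
# (sambar-muntjac) and one asymmetric commensal pair (wild boar tracking
# elephant activity zones).
n_sites: 67
n_days: 365
start_date: "2022-06-01"
species:
  - name: elephant
    psi: 0.60
    mu: 6
    k: 1.0
    activity:
      - {weight: 0.5, mean_h: 6, kappa: 3.0}
      - {weight: 0.5, mean_h: 19, kappa: 3.0}
  - name: sambar
    psi: 0.75
    mu: 8
    k: 1.0
    activity:
      - {weight: 1.0, mean_h: 20, kappa: 1.5}
  - name: muntjac
    psi: 0.65
    mu: 6
    k: 1.0
    activity:
      - {weight: 1.0, mean_h: 10, kappa: 1.5}
  - name: wild_boar
    psi: 0.45
    mu: 7
    k: 0.8
    activity:
      - {weight: 1.0, mean_h: 14, kappa: 1.0}
  - name: squirrel
    psi: 0.20
    mu: 1.5
    k: 1.0
    activity:
      - {weight: 0.5, mean_h: 8, kappa: 2.0}
      - {weight: 0.5, mean_h: 16, kappa: 2.0}
  - name: macaque
    psi: 0.33
    mu: 3.5
    k: 0.8
    activity:
      - {weight: 1.0, mean_h: 12, kappa: 1.5}
  - name: pigtailed_macaque
    psi: 0.13
    mu: 2
    k: 1.0
    activity:
      - {weight: 1.0, mean_h: 11, kappa: 2.0}
  - name: porcupine
    psi: 0.24
    mu: 3.5
    k: 0.8
    activity:
      - {weight: 1.0, mean_h: 1, kappa: 2.0}
  - name: brush_tailed_porcupine
    psi: 0.15
    mu: 3
    k: 1.0
    activity:
      - {weight: 1.0, mean_h: 0, kappa: 2.5}
  - name: junglefowl
    psi: 0.18
    mu: 8
    k: 0.5
    activity:
      - {weight: 0.5, mean_h: 7, kappa: 2.0}
      - {weight: 0.5, mean_h: 17, kappa: 2.0}
  - name: leopard_cat
    psi: 0.15
    mu: 1.2
    k: 1.0
    activity:
      - {weight: 1.0, mean_h: 23, kappa: 1.5}
  - name: serow
    psi: 0.10
    mu: 3
    k: 1.0
    activity:
      - {weight: 0.5, mean_h: 5, kappa: 1.5}
      - {weight: 0.5, mean_h: 18, kappa: 1.5}
associations:
  - {a: sambar, b: muntjac, phi: 0.55}
  - {a: elephant, b: wild_boar, phi: 0.72}
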
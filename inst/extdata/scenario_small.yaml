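# Small synthetic scenario: 6 focal species over 10 years, a planted positive
# habitat-breadth effect on the true occupancy trends, growing list lengths.
seed: 42
out_dir: "occutrend_smoke"
window:
  start: 2000
  end: 2009
min_years: 3
scenario:
  n_species: 6
  n_sites: 40
  psi_mid: 0.4
  traits:
    effects:
      habitat_breadth: 0.01
    lambda_true: 0
    noise_sd: 0.002
  effort:
    visits_per_site_year: 2
    list_mean_start: 3
    list_mean_end: 5
    n_background: 40
occupancy:
  n_chains: 3
  n_iter: 900
  n_burnin: 300
  thin: 1
  n_adapt: 200
comparative:
  n_iter: 500
  traits_include: [status, habitat_breadth]
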
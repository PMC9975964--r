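# Three-scenario demo configuration: 2018 baseline, 2030 business-as-usual
# (BAU), 2030 mitigation-and-adaptation (M&A). Concentrations in ug m-3,
# energy in TWh, areas in km2, temperatures in deg C.
grid:
  n_rows: 32
  n_cols: 32
  cell_area: 4.2
seeds:
  background: 101
  population: 202
  monitors: 303
background:
  spatial_sd: 12
  correlation_length: 3
point_source:
  # In-city coal plant. Source-cell contribution and decay length are set so
  # the plume accounts for roughly 10% of the city-mean concentration,
  # consistent with the ~12% industrial share of urban PM2.5; both are
  # knobs, not measured values.
  row: 16
  col: 16
  monthly_contribution: 28
  decay_length: 6
population:
  gradient_weight: 0.8
  dispersion: 0.5
  ages_2018:
    total_0_99: 8459139
    total_25_99: 6344354
    total_30_99: 5921397
  ages_2030:
    total_0_99: 9308479
    total_25_99: 7488672
    total_30_99: 7116333
baseline_mortality:
  rate: 684.21
  age_band: "30_99"
reference: baseline_2018
attainment_scenario: bau_2030
scenarios:
  baseline_2018:
    emission_scale: 1.0
    population_year: 2018
    season_means: {Jan: 74.46, May: 69.72, Jul: 38.95, Oct: 86.20}
    climate: {average_temperature: 27.58, wind_speed_10m: 3.58, relative_humidity_2m: 55.13}
    energy: {tpp_supply: 1.70, surat_supply: 4.43, renewable_supply: 0.73, cooling_demand: 1.46, added_cool_roof_area: 0}
  bau_2030:
    emission_scale: 1.06
    population_year: 2030
    season_means: {Jan: 92.83, May: 66.51, Jul: 39.52, Oct: 75.15}
    climate: {average_temperature: 28.39, wind_speed_10m: 3.38, relative_humidity_2m: 53.10}
    energy: {tpp_supply: 2.10, surat_supply: 5.26, renewable_supply: 6.63, cooling_demand: 4.22, added_cool_roof_area: 0}
  ma_2030:
    emission_scale: 0.0
    population_year: 2030
    season_means: {Jan: 92.42, May: 66.37, Jul: 38.13, Oct: 74.95}
    climate: {average_temperature: 28.39, wind_speed_10m: 3.38, relative_humidity_2m: 53.10}
    energy: {tpp_supply: 0.0, surat_supply: 5.26, renewable_supply: 8.73, cooling_demand: 4.01, added_cool_roof_area: 20.60}
erfs:
  pope:
    family: loglinear
    rr_per_10: 1.06
    ci: [1.02, 1.11]
    endpoint: all-cause
    age_band: "30_99"
  turner:
    family: loglinear
    rr_per_10: 1.06
    ci: [1.04, 1.08]
    endpoint: all-cause
    age_band: "30_99"
  burnett:
    family: gemm
    theta: 0.143
    se: 0.01807
    alpha: 1.6
    mu: 15.5
    nu: 36.8
    c0: 2.4
    endpoint: non-accidental
    age_band: "25_99"
targets: [NCAP, NAAQS, WHO_AQG]
monitors:
  n_monitors: 10
  n_days: 30
  noise_sd: 5
  bias_by_season:
    winter: 0.30
    pre-monsoon: 0.25
    monsoon: 0.20
    post-monsoon: 0.005
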
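seed: 1.0
params:
  horizon: 20.0
  discount_rate: 0.05
  wage: 17.33
  mortality: 0.005
  clear_radius: 1.0
  clearing_cost: 300.0
  crop_yield_factor: 1.0
  agroforestry_investment_factor: 1.0
  rice_yield: 3148.0
  rice_price: 0.45
  rice_inputs_annual: 250.0
  rice_inputs_year0: 345.0
  rice_labour: 32.0
  maize_yield: 3083.0
  maize_price: 0.5
  maize_inputs_annual: 450.0
  maize_inputs_year0: 919.0
  maize_labour: 22.0
  stocking_base: 2.0
  beef_gain: 160.0
  beef_price: 1.85
  cattle_cost_per_cow: 387.0
  pasture_establishment: 220.0
  pasture_inputs_annual: 50.0
  pasture_labour: 8.0
  teak_density: 1110.0
  teak_thin_years:
  - 4.0
  - 10.0
  teak_thin_fractions:
  - 0.6
  - 0.5
  teak_vol_thin:
  - 0.008
  - 0.07
  teak_vol_harvest: 0.62
  teak_price: 180.0
  teak_seedling_cost: 0.8
  teak_establishment_inputs: 476.0
  teak_inputs_annual: 30.0
  alley_density: 555.0
  alley_thin_years:
  - 5.0
  - 10.0
  alley_thin_fractions:
  - 0.5
  - 0.5
  alley_vol_thin:
  - 0.015
  - 0.09
  alley_vol_harvest: 0.55
  alley_guard_cost: 150.0
  alley_tree_inputs_annual: 20.0
  alley_crop_full_years:
  - 0.0
  - 1.0
  - 2.0
  alley_crop_half_years:
  - 6.0
  - 11.0
  alley_crop_half_factor: 0.5
  silvo_density: 200.0
  silvo_vol_harvest: 0.35
  cedar_price: 180.0
  silvo_pasture_area: 0.95
  silvo_canopy_end: 0.36
  silvo_canopy_yield_factor: 0.5
  silvo_seedling_cost: 0.7
  silvo_guard_cost: 60.0
  silvo_pest_inputs: 20.0
  silvo_prune_inputs: 10.0
  energy_rice: 2.0
  energy_maize: 3.2
  energy_beef: 2.9
  history_years: 20.0
  history_cv:
    rice_yield: 0.18
    rice_price: 0.1
    maize_yield: 0.25
    maize_price: 0.2
    beef_yield: 0.02
    beef_price: 0.02
    teak_price: 0.22
    cedar_price: 0.15
  history_trend:
    rice_yield: 0.005
    rice_price: 0.01
    maize_yield: 0.005
    maize_price: 0.01
    beef_yield: 0.0
    beef_price: 0.005
    teak_price: 0.015
    cedar_price: 0.01
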
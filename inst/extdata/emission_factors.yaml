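gwp:
  CO2: 1.0
  CH4: 28.0
  N2O: 298.0
feed_cf_per_kg:
  corn: 0.37
  soybean_meal: 0.11
  wheat_bran: 0.26
  compound_and_other: 0.55
  fishmeal: 1.78
fertilizer_production:
  'N': 2.12
  P: 0.64
  K: 0.18
n2o_direct_factor: 0.01
n2o_indirect_factor: 0.003
volatilization_rate_cultivation: 0.05
urea_co2: 0.02
pesticide_cf: 12.44
film_cf: 22.72
irrigation_kwh_per_ha:
  corn: 368.7
  soybean: 38.7
  wheat: 839.4
fuel_l_per_ha:
  corn: 67.85
  soybean: 45.96
  wheat: 78.8
diesel_kg_per_l: 0.84
energy_cf:
  electricity: 0.88
  coal: 2.05
  diesel: 3.18
byproduct_energy_mj_per_kg:
  soybean_meal: 13.82
  wheat_bran: 4.15
transport_ef:
  light: 0.185
  medium: 0.197
  heavy: 0.321
enteric_baseline: 1.0
reference_weight: 105.0
manure_ch4_factor: 0.005
manure_n2o_direct_by_system:
  open_lagoon: 0.0
  indoor_storage: 0.002
  solid_storage: 0.005
  liquid_slurry_crust: 0.005
  liquid_slurry_no_crust: 0.0
  anaerobic_digester: 0.0
  aerobic_natural: 0.01
  aerobic_forced: 0.005
  composting_container: 0.006
  composting_intensive: 0.1
  composting_passive: 0.01
volatilization_rate_manure: 0.01
leaching_rate_manure: 0.05
leaching_n2o_factor: 0.0075
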
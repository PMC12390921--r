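schema: fortcost-parameter-book/1
book_id: ethiopia-s1-iodized
scenario: s1-current-consumption
horizon:
  start: 2024
  end: 2033
phase_in_years: 0
program:
  program_id: iodized
  concentrations:
    iodine: 30.0
    folic_acid: 0.0
    vitamin_b12: 0.0
    zinc: 0.0
demand:
  population_by_year:
    '2024': 126202000.0
    '2025': 128852242.0
    '2026': 131558139.0
    '2027': 134320860.0
    '2028': 137141598.0
    '2029': 140021572.0
    '2030': 142962025.0
    '2031': 145964227.0
    '2032': 149029476.0
    '2033': 152159095.0
  per_capita_salt_g_per_day: 6.7
  compliance_fraction: 0.89
  days_per_year: 365.0
finance:
  discount_rate: 0.03
  equipment_life_years: 10.0
  base_currency_year: 2021
  usd_deflator_by_year:
    '2019': 104.0
    '2020': 105.400000000000006
    '2021': 110.200000000000003
  etb_cpi_by_year:
    '2019': 184.0
    '2020': 221.699999999999989
    '2021': 281.100000000000023
  etb_per_usd_base_year: 43.729999999999997
premix:
  sprayed_nutrients:
  - iodine
  extruded_nutrients: []
  extruded_inclusion_rate_kg_per_mt: 0.0
  extruded_price_per_kg: 0.0
  shipping_handling_per_mt_salt: 0.0
  overage_fraction: 0.0
  catalog:
  - nutrient: iodine
    compound: potassium iodate
    nutrient_mass_fraction: 0.592990654205607
    price_per_kg_compound: 65.55126652605145
  - nutrient: folic_acid
    compound: folic acid
    nutrient_mass_fraction: 1.0
    price_per_kg_compound: 90.993653137656224
  - nutrient: vitamin_b12
    compound: cyanocobalamin
    nutrient_mass_fraction: 1.0
    price_per_kg_compound: 6000.0
  - nutrient: zinc
    compound: zinc oxide
    nutrient_mass_fraction: 0.803391496682232
    price_per_kg_compound: 3.0
activities:
- activity_id: premix
  label: Premix, including shipping and taxes
  phase: recurring
  stakeholder: industry
  category: premix
  cost_rule:
    kind: premix
  active_years:
    from: 2024
    to: 2033
- activity_id: refinery_fortification
  label: Salt refinery fortification costs, including labor, power/fuel, annualized
    equipment costs, and maintenance costs
  phase: recurring
  stakeholder: industry
  category: refinery_fortification
  cost_rule:
    kind: fixed_annual
    amount: 546000.0
  active_years:
    from: 2024
    to: 2033
- activity_id: refinery_qaqc
  label: Salt refinery fortification QA/QC activities
  phase: recurring
  stakeholder: industry
  category: refinery_qaqc
  cost_rule:
    kind: fixed_annual
    amount: 125000.0
  active_years:
    from: 2024
    to: 2033
- activity_id: refinery_training
  label: Salt refinery internal training/retraining
  phase: recurring
  stakeholder: industry
  category: refinery_training
  cost_rule:
    kind: fixed_annual
    amount: 22000.0
  active_years:
    from: 2024
    to: 2033
- activity_id: refinery_admin
  label: Salt refinery management, administration, and overhead related to fortification
  phase: recurring
  stakeholder: industry
  category: refinery_admin
  cost_rule:
    kind: fixed_annual
    amount: 347000.0
  active_years:
    from: 2024
    to: 2033
- activity_id: gov_refinery_monitoring
  label: Government inspections and monitoring of salt refineries
  phase: recurring
  stakeholder: government
  category: gov_refinery_monitoring
  cost_rule:
    kind: fixed_annual
    amount: 8000.0
  active_years:
    from: 2024
    to: 2033
- activity_id: gov_import_monitoring
  label: Government monitoring of imported salt
  phase: recurring
  stakeholder: government
  category: gov_import_monitoring
  cost_rule:
    kind: fixed_annual
    amount: 2000.0
  active_years:
    from: 2024
    to: 2033
- activity_id: gov_market_monitoring
  label: Government monitoring of salt at markets and other retail outlets
  phase: recurring
  stakeholder: government
  category: gov_market_monitoring
  cost_rule:
    kind: fixed_annual
    amount: 2000.0
  active_years:
    from: 2024
    to: 2033
- activity_id: gov_household_monitoring
  label: Government household monitoring
  phase: recurring
  stakeholder: government
  category: gov_household_monitoring
  cost_rule:
    kind: fixed_annual
    amount: 14000.0
  active_years:
    from: 2024
    to: 2033
- activity_id: social_marketing
  label: Social marketing/advocacy
  phase: recurring
  stakeholder: government
  category: social_marketing
  cost_rule:
    kind: fixed_annual
    amount: 9000.0
  active_years:
    from: 2024
    to: 2033
- activity_id: gov_capacity_building
  label: Capacity building/training for food control agency personnel/monitors/laboratory
    technicians
  phase: recurring
  stakeholder: government
  category: gov_capacity_building
  cost_rule:
    kind: fixed_annual
    amount: 14000.0
  active_years:
    from: 2024
    to: 2033
- activity_id: gov_admin
  label: Government management, administration, and overhead
  phase: recurring
  stakeholder: government
  category: gov_admin
  cost_rule:
    kind: fixed_annual
    amount: 24000.0
  active_years:
    from: 2024
    to: 2033
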
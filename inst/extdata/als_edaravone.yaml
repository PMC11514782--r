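# Cost-utility model: sublingual (SL, comparator) vs intravenous (IV,
# reference) edaravone for amyotrophic lateral sclerosis, Chinese setting.
# Base case: both formulations administered at home.
#
# The transition table is stored exactly as printed in its source, where
# the COLUMNS index the from-state (each column sums to 1); the loader
# transposes it into the engine's row-stochastic convention.
name: ALS edaravone SL vs IV (base case)
currency: CNY
states: [stage1, stage2, stage3, stage4, death]
absorbing_state: death
start_distribution: [1, 0, 0, 0, 0]
cycle_length_years: 0.25
n_cycles: 80
discount_rate_annual: 0.05
discount_from: first_cycle
start_age_years: 54
transition:
  orientation: columns-are-from
  probabilities:
    - [0.677, 0.000, 0.000, 0.000, 0.000]
    - [0.217, 0.706, 0.000, 0.000, 0.000]
    - [0.064, 0.213, 0.830, 0.000, 0.000]
    - [0.038, 0.063, 0.118, 0.820, 0.000]
    - [0.004, 0.018, 0.052, 0.180, 1.000]
utilities:
  stage_utilities:
    stage1: 0.740
    stage2: 0.630
    stage3: 0.510
    stage4: 0.370
  # reported ratio of the route factors 0.99 (oral) / 0.97 (IV), 3 dp
  comparator_adjustment_coefficient: 1.021
arms:
  reference:
    name: IV
    administration_setting: home
    utility_route_factor: 0.97
    schedule:
      course_length_days: 28
      first_course_admin_days: 14
      subsequent_course_admin_days: 10
      doses_per_day: 2
      # 12 courses/year (3 per quarterly cycle); device amortization below
      # keeps the conventional 13 courses/year divisor
      courses_per_cycle: 3
      courses_per_year_for_amortization: 13
    costs:
      unit_drug_price: 86.83
      device_insertion_cost: 1847.96   # PICC, replaced once per year
      device_insertions_per_year: 1
      device_maintenance_cost: 103.17  # PICC maintenance, twice per course
      maintenance_events_per_course: 2
      transport_cost_per_visit: 0
      adverse_events:
        - {name: erythra, probability: 0.0070, cost: 20.00}
        - {name: liver_damage, probability: 0.0281, cost: 1985.50}
        - {name: kidney_damage, probability: 0.0000, cost: 613.00}
      indirect:
        employment_rate: 0.15
        hours_lost_per_visit: 6.23
        hourly_wage: 18.44
      visit_policy:
        # calibrated so the incremental cost matches the published lifetime
        # totals; IV at home still needs periodic supervised infusion /
        # catheter care encounters, SL does not
        productivity_visits_per_course: 7
        transport_visits_per_course: 0
  comparator:
    name: SL
    administration_setting: home
    utility_route_factor: 0.99
    schedule:
      course_length_days: 28
      first_course_admin_days: 14
      subsequent_course_admin_days: 10
      doses_per_day: 2
      courses_per_cycle: 3
      courses_per_year_for_amortization: 13
    costs:
      unit_drug_price: 130.00
      device_insertion_cost: 0
      device_insertions_per_year: 1
      device_maintenance_cost: 0
      maintenance_events_per_course: 0
      transport_cost_per_visit: 0
      adverse_events:
        - {name: erythra, probability: 0.0005, cost: 20.00}
        - {name: liver_damage, probability: 0.0024, cost: 1985.50}
        - {name: kidney_damage, probability: 0.0028, cost: 613.00}
      indirect:
        employment_rate: 0.15
        hours_lost_per_visit: 6.23
        hourly_wage: 18.44
      visit_policy:
        productivity_visits_per_course: 0
        transport_visits_per_course: 0
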
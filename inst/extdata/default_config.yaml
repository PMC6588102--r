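# Default run configuration.
#
# Natural-history and economic values are uncalibrated placeholders (see the
# `provenance` tag); calibrate() against the target table below is the
# sanctioned way to obtain a parameter set reproducing the published per-arm
# outcomes. Screening uptakes (0.60 status quo, 0.80 navigation program),
# the 3% discount rate, the $50,000/QALY threshold and the 100,000-person
# cohort are the study settings.
schema_version: 1
root_seed: 1
cohort:
  n_persons: 100000
  entry_age_min: 40
  entry_age_max: 70
mortality:
  makeham_c: 0.002
  gompertz_a: 5.0e-05
  gompertz_b: 0.092
  max_age: 100
natural_history:
  provenance: uncalibrated placeholder
  onset_hazard_scale: 0.006
  onset_age_shape: 0.025
  frac_onset_dcis: 0.80
  progression:
    dcis_to_local: 0.35
    local_to_regional: 0.32
    regional_to_distant: 0.30
  symptomatic_detection_prob:
    DCIS: 0.04
    LOCAL: 0.12
    REGIONAL: 0.30
    DISTANT: 0.60
  excess_bc_mortality:
    DCIS: 0.002
    LOCAL: 0.015
    REGIONAL: 0.06
    DISTANT: 0.30
screening:
  status_quo:
    three_year_uptake: 0.60
    program_window_years: 3
    background_uptake: 0.60
    screening_interval_years: 2
    sensitivity_by_stage:
      DCIS: 0.75
      LOCAL: 0.85
      REGIONAL: 0.90
      DISTANT: 0.95
    specificity: 0.92
    program_flag: no
  program:
    three_year_uptake: 0.80
    program_window_years: 3
    background_uptake: 0.60
    screening_interval_years: 2
    sensitivity_by_stage:
      DCIS: 0.75
      LOCAL: 0.85
      REGIONAL: 0.90
      DISTANT: 0.95
    specificity: 0.92
    program_flag: yes
economics:
  discount_rate: 0.03
  program_cost_per_participant: 500
  mammogram_cost: 100
  false_positive_workup_cost: 250
  treatment_cost_by_stage:
    DCIS: 12000
    LOCAL: 22000
    REGIONAL: 45000
    DISTANT: 80000
  terminal_care_cost: 40000
  utility_healthy: 0.92
  utility_decrement_by_stage:
    DCIS: 0.05
    LOCAL: 0.10
    REGIONAL: 0.20
    DISTANT: 0.40
cea:
  threshold: 50000
sensitivity:
  rate_from: 0.60
  rate_to: 0.80
  rate_by: 0.01
  cost_from: 0
  cost_to: 6000
  cost_by: 50
  n_persons: 20000
calibration:
  free_parameters:
    - onset_hazard_scale
    - symptomatic_detection_scale
    - excess_bc_mortality_scale
    - treatment_cost_scale
    - utility_decrement_scale
    - program_cost_per_participant
  targets:
    - {quantity: cost, arm: program, value: 2632.90, weight: 1}
    - {quantity: life_expectancy, arm: program, value: 23.03, weight: 1}
    - {quantity: qaly, arm: program, value: 14.09, weight: 1}
    - {quantity: cost, arm: status_quo, value: 2508.10, weight: 1}
    - {quantity: life_expectancy, arm: status_quo, value: 22.32, weight: 1}
    - {quantity: qaly, arm: status_quo, value: 14.05, weight: 1}
  n_eval: 20000
  n_confirm: 100000
  max_evaluations: 150
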
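# Dutch base-case scenario: second-line advanced melanoma, TIL cell therapy
# versus ipilimumab, modified societal perspective, 2021 euros.
# Survival curves are log-logistic fits to the modeled month 3-12 PFS/OS
# probabilities shipped in table1_survival_points.csv.
scenario:
  country_label: Netherlands
  currency_label: EUR
  discount_rate_costs: 0.04
  discount_rate_effects: 0.015
  wtp_threshold: 80000
  # baseline cohort age is not part of the published inputs; 59 years is a
  # documented placeholder consistent with the trial population
  baseline_age_years: 59
  cycle_length_years: 0.25
  friction_period_days: 78.9   # provenance of the productivity-loss amounts
arms:
  - name: TIL
    pfs_curve:
      family: loglogistic
      points_csv: table1_survival_points.csv
      arm: TIL
      endpoint: PFS
    os_curve:
      family: loglogistic
      points_csv: table1_survival_points.csv
      arm: TIL
      endpoint: OS
    treatment_costs:
      one_time_items:
        screening: 3822
        til_isolation: 2043
        til_production: 67547
        admission_follow_up: 44528
      death_cost: 1516
      follow_up_stop_years: 5
    societal_costs:
      first_cycle_amount: 4476     # direct patient 227 + informal care 710 + productivity 3539
      per_cycle_amount: 256        # direct patient 82 + informal care 99 + productivity 75
      annual_amount: 385           # copay
    pfs_utilities:
      timepoints: [0, 3, 6, 9, 12]
      values: [0.874, 0.879, 0.885, 0.881, 0.887]
      carry_forward: true
      pre_death_utility: 0.665
    next_line_mix:
      - {label: ipilimumab_monotherapy, course_cost: 66388, utility: 0.764, proportion: 0.20}
      - {label: braf_mek_inhibitor, course_cost: 101224, utility: 0.844, proportion: 0.20}
      - {label: ipilimumab_nivolumab, course_cost: 72514, utility: 0.695, proportion: 0.11}
      - {label: pembrolizumab, course_cost: 54571, utility: 0.707, proportion: 0.01}
      - {label: no_treatment, course_cost: 0, utility: 0.832, proportion: 0.43}
      # "other" = 25% temozolomide (utility 0.730) + 75% ipilimumab/pembrolizumab;
      # no utility is published for the ipilimumab/pembrolizumab component, so the
      # component-weighted value uses the mean of the published ipilimumab (0.764)
      # and pembrolizumab (0.707) utilities for it: 0.25*0.730 + 0.75*0.7355
      - {label: other, course_cost: 96448, utility: 0.734125, proportion: 0.05}
  - name: Ipilimumab
    pfs_curve:
      family: loglogistic
      points_csv: table1_survival_points.csv
      arm: Ipilimumab
      endpoint: PFS
    os_curve:
      family: loglogistic
      points_csv: table1_survival_points.csv
      arm: Ipilimumab
      endpoint: OS
    treatment_costs:
      one_time_items:
        screening: 2507
        ipilimumab_treatment: 75316
      death_cost: 1516
      follow_up_stop_years: 5
    societal_costs:
      first_cycle_amount: 4665     # direct patient 210 + informal care 916 + productivity 3539
      per_cycle_amount: 201        # direct patient 27 + informal care 99 + productivity 75
      annual_amount: 385           # copay
    pfs_utilities:
      timepoints: [0, 3, 6, 9, 12]
      values: [0.838, 0.840, 0.841, 0.849, 0.828]
      carry_forward: true
      pre_death_utility: 0.665
    next_line_mix:
      - {label: ipilimumab_rechallenge, course_cost: 66388, utility: 0.764, proportion: 0.02}
      - {label: braf_mek_inhibitor, course_cost: 101224, utility: 0.844, proportion: 0.29}
      - {label: pembrolizumab, course_cost: 54571, utility: 0.707, proportion: 0.10}
      - {label: no_treatment_or_trial, course_cost: 0, utility: 0.764, proportion: 0.57}
      # "other" = 50% dacarbazine (utility 0.791) + 50% temozolomide (0.730)
      - {label: other, course_cost: 6814, utility: 0.7605, proportion: 0.02}
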
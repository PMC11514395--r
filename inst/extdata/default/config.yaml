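# Base-case configuration. Every table is a UTF-8 CSV with a header row and
# "." as decimal separator. Costs are 2024 Qatari Riyal (QAR); 3.64 QAR = 1 USD.
tables:
  prevalence: prevalence.csv
  clinical: clinical.csv
  disposition: disposition.csv
  acquisition: acquisition.csv
  costs_short: costs_short.csv
  costs_long: costs_long.csv
  utilities: utilities.csv
  transitions: transitions.csv
markov:
  start_age: 48
  end_age: 81
  cycle_length: 0.25
  discount_rate: 0.03
  cohort_size: 15000
  variant: reconciled        # or "as_printed"
  event_cost_cadence: incident  # or "per_cycle" (relapse event charged per occupied cycle)
  age_trends: true
  half_cycle: false
mortality:
  # Synthetic stand-in schedule (no local life table is bundled): Gompertz-like
  # annual mortality, base_rate at base_age, doubling every doubling_years.
  # Replace with a CSV (columns age_mid, rate) via `table:` for real data.
  model: gompertz
  base_rate: 0.002
  base_age: 48
  doubling_years: 8
  age_from: 45
  age_to: 85
  band_width: 5
  fit_degree: 2
  synthetic: true
settings:
  wtp: 546000                # QAR per QALY (USD 150,000 x 3.64)
  usd_to_qar: 3.64
  gene_weights:
    CYP2D6: 0.5
    CYP2C19: 0.5
  count_alternative_success: false
  discontinuation_half_rule: true
  duloxetine_course_cost: 90
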
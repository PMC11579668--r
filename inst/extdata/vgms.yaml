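# Virtual glycemic management service: remote daily chart review of
# inpatients flagged by dysglycemia reporting criteria.  Published effects
# were reported on patient-days with one or more hypoglycemic events and
# must be calibrated onto the event-level measure.  Annual salaries are
# illustrative mid-range figures (the source analysis did not print
# salary levels); edit to local payroll values before costing.
name: vgms
target: adult_nonobstetric
published_effect:
  outcome_measure: patient_days
  rr_total_hypo: 0.64
  rr_severe_hypo: 0.31
elicited_rrs:
  realistic:
    total_hypo: 0.76
    severe_hypo: 0.50
  optimistic:
    total_hypo: 0.70
    severe_hypo: 0.20
  pessimistic:
    total_hypo: 0.82
    severe_hypo: 0.75
reporting_criteria:
  min_hyper: 2               # >= 2 hyperglycemia events (> 15.0 mmol/L)
  min_hypo: 1                # or >= 1 hypoglycemia event (< 4.0 mmol/L)
  window_days: 1             # in the previous 24 hours (one model day)
hac_fraction: 0.240
resources:
  staff:
    - role: endocrinology registrar
      fte: 0.2
      annual_salary: 120000
      funded: true
    - role: CDE nurse
      fte: 0.2
      annual_salary: 100000
      funded: true
    - role: CDE pharmacist
      fte: 0.2
      annual_salary: 110000
      funded: true
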
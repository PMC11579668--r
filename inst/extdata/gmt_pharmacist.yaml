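# Pharmacist-led peri-operative glycemic management team: takes over
# glycemic management of surgical (incl. ICU) patients on surgeon request.
# Two published relative-risk variants exist for the same study
# (preintervention vs year 1 analyses reported separately: 0.46 and 0.38
# on patients with >= 1 hypoglycemic event); this fixture carries the more
# conservative 0.46, with the alternative noted for sensitivity analysis.
# Excluded after the preliminary evaluation on cost grounds, so no
# elicited scenarios exist.
name: gmt_pharmacist
target: surgical_incl_icu
published_effect:
  outcome_measure: patients
  rr_total_hypo: 0.46       # alternative reported variant: 0.38
hac_fraction: 0.255
resources:
  staff:
    - role: pharmacist
      fte: 2.0
      annual_salary: 105000  # 2 FTE, AU$210,000 total per year
      funded: true
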
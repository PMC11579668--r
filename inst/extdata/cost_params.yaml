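# Cost and time parameters (AUD, minutes, hours) for the cost-consequence
# analysis.  bed_day_cost is the adopted value; the per-diem price weight
# and national efficient price it can be derived from are kept alongside
# for sensitivity analysis (their product, 1478.17, differs slightly).
penalty_per_hac: 1132
bed_day_cost: 1450
price_weight: 0.2641
national_efficient_price: 5597
bed_days_per_fully_prevented: 3
nursing_min_nonsevere: 5
nursing_min_severe: 25
survey_minutes_per_event: 1
fte_hours_per_week: 38
weeks_per_year: 52
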
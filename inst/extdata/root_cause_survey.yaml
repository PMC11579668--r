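# Root cause survey with targeted education: automated EMR pop-up survey
# completed by nurses after each hypoglycemic event, feeding targeted
# education.  Published effect reported directly on the common event-level
# measure (hypoglycemic PoC-BGL measurements); no severe-specific effect
# was published, so the severe channel inherits the total effect.
name: root_cause_survey
target: adult_nonobstetric
published_effect:
  outcome_measure: events
  rr_total_hypo: 0.68
elicited_rrs:
  realistic:
    total_hypo: 0.85
  optimistic:
    total_hypo: 0.80
  pessimistic:
    total_hypo: 0.90
hac_fraction: 0.240
resources:
  once_off_hours: 88          # develop and test the survey in the EMR
  per_cycle_components:
    nursing: 25               # completing the surveys (1 min each)
    implementation: 19        # roll-out, analysis, education, audit
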
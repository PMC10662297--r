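# SYNTHETIC scenario catalogue (illustrative, not observed elicitation
# bounds). Eight one-way probability scenarios in the style of a
# questionnaire-bound deterministic sensitivity analysis: 1P/2P vary the
# initial X-ray classification (clinician behaviour changes when IMA is
# known to be available later), 3P/4P vary the loosening rate found at
# follow-up (IMA or second X-ray), 5P/6P vary the share receiving immediate
# surgery after the initial X-ray, 7P/8P vary surgery acceptance at
# follow-up. Probability vectors are renormalised on load. Replace with your
# own elicitation summaries for a calibrated analysis.
scenarios:
  - id: 1P
    overrides:
      "prob:initial_xray": [0.60, 0.10, 0.30]
  - id: 2P
    overrides:
      "prob:initial_xray": [0.80, 0.10, 0.10]
  - id: 3P
    overrides:
      "prob:ima_followup": [0.15, 0.85]
      "prob:xray_followup": [0.15, 0.85]
  - id: 4P
    overrides:
      "prob:ima_followup": [0.45, 0.55]
      "prob:xray_followup": [0.45, 0.55]
  - id: 5P
    overrides:
      "prob:initial_xray": [0.85, 0.05, 0.10]
  - id: 6P
    overrides:
      "prob:initial_xray": [0.55, 0.25, 0.20]
  - id: 7P
    overrides:
      "prob:loose_after_ima": [0.60, 0.40]
      "prob:loose_after_followup": [0.60, 0.40]
  - id: 8P
    overrides:
      "prob:loose_after_ima": [0.90, 0.10]
      "prob:loose_after_followup": [0.90, 0.10]
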
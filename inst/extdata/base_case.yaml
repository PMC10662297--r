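# Base-case model: X-ray/IMA pathway vs X-ray/X-ray follow-up for suspected
# aseptic loosening after total hip arthroplasty. Transition probabilities,
# unit costs (SEK) and HRQoL trajectory parameters are the published
# base-case values; per-branch cost compositions are the package's default
# reading of the pathway resource use and can be recalibrated here.
horizon_years: 2
thresholds: [500000, 700000]
costs:
  X-ray: 1029
  Physician visit: 2635
  IMA: 9000
  Surgery: 152187
  CT: 4353
  Follow-up: 5318
  Other treatment: 5318
profiles:
  immediate_surgery:
    type: plateau
    baseline: 0.62
    plateau: 0.8
    plateau_month: 18
  untreated_loosening:
    type: decline
    baseline: 0.62
    step_per_6mo: 0.0528
  delayed_surgery:
    type: delayed
    baseline: 0.62
    step_per_6mo: 0.0528
    surgery_month: 12
    plateau: 0.8
  other_treatment:
    type: constant
    baseline: 0.62
    level: 0.65
arms:
  - label: X-ray/IMA
    root:
      label: initial_xray
      branches:
        - label: loose
          p: 0.7
          node:
            label: loose_after_xray
            branches:
              - label: surgery
                p: 0.75
                terminal:
                  components: [Physician visit, X-ray, Surgery]
                  profile: immediate_surgery
              - label: other treatment
                p: 0.25
                terminal:
                  components: [Physician visit, X-ray, Other treatment]
                  profile: untreated_loosening
        - label: not loose
          p: 0.15
          terminal:
            components: [Physician visit, X-ray]
            profile: other_treatment
        - label: uncertain
          p: 0.15
          node:
            label: ima_followup
            branches:
              - label: loose
                p: 0.3
                node:
                  label: loose_after_ima
                  branches:
                    - label: surgery
                      p: 0.75
                      terminal:
                        components: [Physician visit, X-ray, Physician visit,
                                     CT, IMA, Surgery]
                        profile: immediate_surgery
                    - label: other treatment
                      p: 0.25
                      terminal:
                        components: [Physician visit, X-ray, Physician visit,
                                     CT, IMA, Other treatment]
                        profile: untreated_loosening
              - label: not loose
                p: 0.7
                terminal:
                  components: [Physician visit, X-ray, Physician visit, CT,
                               IMA]
                  profile: other_treatment
  - label: X-ray/X-ray
    root:
      label: initial_xray
      branches:
        - label: loose
          p: 0.7
          node:
            label: loose_after_xray
            branches:
              - label: surgery
                p: 0.75
                terminal:
                  components: [Physician visit, X-ray, Surgery]
                  profile: immediate_surgery
              - label: other treatment
                p: 0.25
                terminal:
                  components: [Physician visit, X-ray, Other treatment]
                  profile: untreated_loosening
        - label: not loose
          p: 0.15
          terminal:
            components: [Physician visit, X-ray]
            profile: other_treatment
        - label: uncertain
          p: 0.15
          node:
            label: xray_followup
            branches:
              - label: loose
                p: 0.3
                node:
                  label: loose_after_followup
                  branches:
                    - label: surgery
                      p: 0.75
                      terminal:
                        components: [Physician visit, X-ray, Physician visit,
                                     X-ray, Surgery]
                        profile: delayed_surgery
                    - label: other treatment
                      p: 0.25
                      terminal:
                        components: [Physician visit, X-ray, Physician visit,
                                     X-ray, Other treatment]
                        profile: untreated_loosening
              - label: not loose
                p: 0.7
                terminal:
                  components: [Physician visit, X-ray, Physician visit, X-ray]
                  profile: other_treatment
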
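description: >
  Synthetic reconstruction of one Australian-style training preparation
  (rest, pre-training, progressive, race-fit). Speeds and distances are
  plausible demonstration values, not a published programme table.
phases:
- kind: rest
  duration_days: 44
- kind: pre-training
  duration_days: 28
  workouts:
  - speed_m_s: 4.0
    distance_m: 1500
    per: day
- kind: progressive
  duration_days: 61
  workouts:
  - speed_m_s: 7.5
    distance_m: 2000
    per: day
  - speed_m_s: 11.8
    distance_m: 500
    per: week
  - speed_m_s: 13.8
    distance_m: 500
    per: week
- kind: race-fit
  duration_days: 61
  workouts:
  - speed_m_s: 7.5
    distance_m: 2000
    per: day
  - speed_m_s: 13.8
    distance_m: 500
    per: week
  - speed_m_s: 16.0
    distance_m: 500
    per: week
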
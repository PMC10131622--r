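{
  "invited": 130,
  "baseline": 34,
  "second_selfassessment": 9,
  "third_selfassessment": 2,
  "mauq_respondents": 8,
  "modules_performed": 112,
  "users_performing_modules": 25
}
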
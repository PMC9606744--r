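# Service-quality determinant -> TRIZ improving-parameter map for the
# bundled combined medical and elderly care (CMEC) case, plus the case's
# default worsening parameters and the expert screening roster.
determinants:
  - id: 13
    name: number of nursing staff
    parameter: 26
  - id: 5
    name: service adaptability
    parameter: 35
  - id: 18
    name: service capacity
    parameter: 26
  - id: 7
    name: healthcare workers' attitude
    parameter: 17
  - id: 20
    name: service delivery time
    parameter: 9
worsening: [22, 36]
roster: [1, 4, 21, 25, 27, 10, 28]
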
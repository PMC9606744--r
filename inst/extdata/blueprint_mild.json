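{
  "title": "CMEC service blueprint, elderly with mild illness (synthetic lane-level reconstruction)",
  "scenario": "mild",
  "actions": [
    {"id": "c_contact", "lane": "customer", "label": "Contact nursing staff",
     "successors": ["f_receive"]},
    {"id": "c_diagnostic", "lane": "customer", "label": "Receive diagnostic services",
     "successors": ["c_therapeutic"]},
    {"id": "c_therapeutic", "lane": "customer", "label": "Receive therapeutic services",
     "successors": ["c_rehab"]},
    {"id": "c_rehab", "lane": "customer", "label": "Receive rehabilitation services",
     "successors": []},
    {"id": "f_receive", "lane": "front_stage", "label": "Receive request from the elderly",
     "successors": ["f_arrive"]},
    {"id": "f_arrive", "lane": "front_stage", "label": "Arrive at the bed",
     "successors": ["f_provide", "b_assess"]},
    {"id": "f_provide", "lane": "front_stage", "label": "Provide care services",
     "successors": ["c_diagnostic", "f_rehab"]},
    {"id": "f_rehab", "lane": "front_stage", "label": "Perform rehabilitation activities",
     "successors": ["c_rehab"]},
    {"id": "b_assess", "lane": "back_stage", "label": "Assess health status of the elderly",
     "successors": ["b_equip"]},
    {"id": "b_equip", "lane": "back_stage", "label": "Prepare testing equipment",
     "successors": ["f_provide"]}
  ],
  "failure_points": [
    {"failure_id": "F1", "action_id": "b_assess",
     "note": "Detection of sudden illness in the elderly"},
    {"failure_id": "F2", "action_id": "f_receive",
     "note": "Healthcare worker's response"},
    {"failure_id": "F3", "action_id": "f_provide",
     "note": "Healthcare worker's judgement of patient's condition"},
    {"failure_id": "F4", "action_id": "b_equip",
     "note": "Provision of testing equipment (mild-illness scenario only)"},
    {"failure_id": "F6", "action_id": "f_rehab",
     "note": "Commencing rehabilitation services"}
  ]
}
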
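[
  {
    "name": "escalation",
    "roles": ["results_of_a", "threat_to_b", "results_of_b", "threat_to_a"],
    "edges": [
      ["results_of_a", "threat_to_b", "positive"],
      ["threat_to_b", "results_of_b", "positive"],
      ["results_of_b", "threat_to_a", "positive"],
      ["threat_to_a", "results_of_a", "positive"]
    ],
    "loop_constraints": [
      {
        "roles": ["results_of_a", "threat_to_b", "results_of_b", "threat_to_a"],
        "class": "reinforcing"
      }
    ]
  }
]
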
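{
  "levels": [
    {"label": "NI", "score": 1, "q": 0.0, "o": 0.0, "p": 0.25},
    {"label": "LI", "score": 2, "q": 0.0, "o": 0.25, "p": 0.5},
    {"label": "I", "score": 3, "q": 0.25, "o": 0.5, "p": 0.75},
    {"label": "VI", "score": 4, "q": 0.5, "o": 0.75, "p": 1.0},
    {"label": "EI", "score": 5, "q": 0.75, "o": 1.0, "p": 1.0}
  ],
  "semantics": {
    "S": ["Almost no service failures", "Minor service failures",
          "Moderate service failures", "Critical service failures",
          "Catastrophic service failures"],
    "O": ["Extremely unlikely service failures", "Very few service failures",
          "Occasional service failures", "Repeated service failures",
          "Frequent service failures"],
    "D": ["Detectable without service failure occurrence or tests",
          "Detectable by a few tests before service failure occurrence",
          "Detectable by multiple tests before service failure occurrence",
          "Detectable once service failure has occurred",
          "Detectable by tests after service failure occurrence"]
  }
}
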
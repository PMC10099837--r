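{
  "negation_cues": ["no", "not", "without", "neither", "nor", "none", "never", "lack", "lacked", "absence", "absent"],
  "connectors": ["although", "though", "even though", "whereas", "while", "but", "however", "nevertheless", "because", "since", "therefore", "moreover", "furthermore", "thus", "hence", "meanwhile"],
  "concessive": ["although", "though", "even though", "whereas", "while", "but", "however", "nevertheless"],
  "modality_markers": ["may", "might", "could", "suggest", "suggests", "suggested", "likely", "possibly", "appear", "appears", "seem", "seems"],
  "neutral_rules": {
    "genotyped": "\\bgenotyp(?:ed|ing)\\b",
    "examined": "\\bexamined\\b",
    "investigated": "\\binvestigated\\b",
    "recruited": "\\brecruited\\b",
    "enrolled": "\\benrolled\\b",
    "study_aim": "\\baim of (?:this|the) study\\b",
    "measured": "\\bmeasured\\b"
  },
  "alpha": 0.05
}
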
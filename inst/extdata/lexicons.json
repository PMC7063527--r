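{
  "version": "mph-1.0",
  "groups": {
    "personal_noun": {
      "first_person": {
        "match_mode": "exact_stem",
        "stems": ["i", "i'", "my", "me", "mine", "myself", "im", "iam"]
      },
      "second_person": {
        "match_mode": "exact_stem",
        "stems": ["you", "you'", "your", "yours", "yourself", "ur"]
      },
      "third_person": {
        "match_mode": "exact_stem",
        "stems": ["he", "he'", "his", "him", "himself", "she", "she'", "her",
                  "hers", "herself", "they", "they'", "their", "theirs",
                  "them", "themselves"]
      },
      "others": {
        "match_mode": "exact_stem",
        "stems": ["boy", "boyfriend", "child", "children", "daughter",
                  "friend", "girl", "girlfriend", "husband", "kid", "son",
                  "wife"]
      }
    },
    "nonmedical": {
      "general": {
        "match_mode": "exact_stem",
        "stems": ["abus", "misus"]
      },
      "motives": {
        "match_mode": "exact_stem",
        "stems": ["allnight", "assign", "clean", "colleg", "cram", "diet",
                  "essay", "exam", "examin", "final", "focus", "highschool",
                  "homework", "loss", "midnight", "midterm", "nighter",
                  "overnight", "paper", "paperwork", "parti", "project",
                  "quiz", "recreat", "school", "shift", "studi", "studyin",
                  "test", "work", "write"]
      },
      "overdose": {
        "match_mode": "exact_stem",
        "stems": ["double", "extra", "overdos", "overus", "pop"]
      },
      "route": {
        "match_mode": "exact_stem",
        "stems": ["crush", "inhal", "inject", "rail", "sniff", "sniffin",
                  "snort", "snortin"]
      },
      "seeking": {
        "match_mode": "exact_stem",
        "stems": ["need", "want", "wish"]
      },
      "obtaining": {
        "match_mode": "exact_stem",
        "stems": ["buy", "sell", "share", "steal", "trade"]
      },
      "coingestion": {
        "match_mode": "exact_stem",
        "stems": ["alcohol", "beer", "bird", "booz", "bull", "caffeine",
                  "cocain", "coffe", "coke", "crack", "crystal", "energi",
                  "energydrink", "espresso", "heroin", "lsd", "marijuana",
                  "monster", "pot", "redbul", "seed", "shot", "tequila",
                  "vodka", "weed", "wine", "xtc"]
      }
    },
    "medical": {
      "medical": {
        "match_mode": "exact_stem",
        "stems": ["addadhd", "adhd", "defici", "diagnos", "diagnosis",
                  "disord", "narcolepsy", "narcolept", "prescribe",
                  "prescript"]
      }
    },
    "side_effect": {
      "general": {
        "match_mode": "exact_stem",
        "stems": ["side", "sideeffect", "advers"]
      },
      "appetite": {
        "match_mode": "exact_stem",
        "stems": ["anorexia", "appetit", "ate", "eat", "eaten", "eatin",
                  "food", "hungry", "lbs", "meal", "skinni", "slim", "starv",
                  "thin", "underweight", "weight"]
      },
      "sleep": {
        "match_mode": "exact_stem",
        "stems": ["asleep", "awak", "insomnia", "insomniac", "sleep",
                  "sleepi", "sleepless", "slept", "tire"]
      },
      "psychiatric": {
        "match_mode": "exact_stem",
        "stems": ["anxieti", "anxious", "depress", "jitter", "jitteri",
                  "nervous", "obsess", "panic", "restless", "shaki",
                  "shakin", "tens", "tension", "worri", "zombie"]
      },
      "heart": {
        "match_mode": "exact_stem",
        "stems": ["beat", "heart", "heartbeat", "heartrat", "palpit"]
      },
      "gastrointestinal": {
        "match_mode": "exact_stem",
        "stems": ["diarrhea", "dri", "nausea", "nauseat", "nauseous",
                  "stomach", "throw", "thrown", "vomit"]
      },
      "neurological": {
        "match_mode": "exact_stem",
        "stems": ["dizzi", "head", "headach", "lighthead", "migrain"]
      },
      "sweating": {
        "match_mode": "exact_stem",
        "stems": ["hot", "sweat", "sweatin"]
      },
      "eye": {
        "match_mode": "exact_stem",
        "stems": ["blurri", "vision", "visual"]
      }
    }
  }
}
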
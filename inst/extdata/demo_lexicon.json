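{
  "iss_terms": [
    "want to die", "wanted to die", "die", "died", "dying",
    "kill myself", "killing myself", "suicide", "suicidal",
    "jump off", "jump out", "jumped", "jumping",
    "end my life", "ending my life", "hurt myself", "self harm",
    "overdose", "cut myself"
  ],
  "negation_cues": ["not", "no", "never", "dont", "don", "didnt", "didn", "wont", "won", "t"],
  "other_subject_cues": ["friend", "friends", "they", "he", "she", "them", "him", "her",
                         "mother", "father", "mom", "dad", "brother", "sister",
                         "classmate", "someone", "people"],
  "past_tense_cues": ["used", "ago", "yesterday", "last", "past", "before",
                      "jumped", "attempted", "died", "tried", "was", "were"],
  "reporting_cues": ["said", "says", "saying", "told", "telling", "heard", "claims"],
  "dream_cues": ["dream", "dreams", "dreamt", "nightmare", "nightmares"]
}
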
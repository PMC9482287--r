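{
  "id": "ko00860",
  "name": "Porphyrin and chlorophyll metabolism: chlorophyll a biosynthesis chain",
  "input": "glutamate",
  "steps": [
    {"step": "HemA",  "ec": "1.2.1.70",   "genes": ["HemA"],                 "product": "L-glutamate 1-semialdehyde"},
    {"step": "HemL",  "ec": "5.4.3.8",    "genes": ["HemL"],                 "product": "5-aminolevulinate"},
    {"step": "HemB",  "ec": "4.2.1.24",   "genes": ["HemB"],                 "product": "porphobilinogen"},
    {"step": "HemC",  "ec": "2.5.1.61",   "genes": ["HemC"],                 "product": "hydroxymethylbilane"},
    {"step": "HemD",  "ec": "4.2.1.75",   "genes": ["HemD"],                 "product": "uroporphyrinogen III"},
    {"step": "HemE",  "ec": "4.1.1.37",   "genes": ["HemE"],                 "product": "coproporphyrinogen III"},
    {"step": "HemF/HemN", "ec": "1.3.3.3","genes": ["HemF", "HemN"],         "product": "protoporphyrinogen IX"},
    {"step": "HemY",  "ec": "1.3.3.4",    "genes": ["HemY"],                 "product": "protoporphyrin IX"},
    {"step": "Mg-chelatase", "ec": "6.6.1.1", "genes": ["chlH", "chlD", "chlI"], "product": "Mg-protoporphyrin IX"},
    {"step": "chlM",  "ec": "2.1.1.11",   "genes": ["chlM"],                 "product": "Mg-protoporphyrin IX 13-monomethyl ester"},
    {"step": "chlE",  "ec": "1.14.13.81", "genes": ["chlE"],                 "product": "divinyl protochlorophyllide"},
    {"step": "DVR",   "ec": "1.3.1.75",   "genes": ["DVR"],                  "product": "protochlorophyllide"},
    {"step": "POR",   "ec": "1.3.1.33",   "genes": ["por"],                  "product": "chlorophyllide a"},
    {"step": "chlG",  "ec": "2.5.1.62",   "genes": ["chlG"],                 "product": "chlorophyll a"}
  ]
}
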
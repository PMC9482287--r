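{
  "id": "ko00195",
  "name": "Photosynthesis (frozen synthetic roster: 63 genes, 30 plastid + 33 nuclear)",
  "components": [
    {
      "name": "Photosystem II",
      "genes": {
        "gene":        ["psbA", "psbB", "psbC", "psbD", "psbE", "psbF", "psbH", "psbI", "psbJ", "psbK", "psbL", "psbM", "psbT", "psbZ", "psbO", "psbP", "psbQ", "psbR", "psbS", "psbW", "psbX", "psbY", "psb27", "psb28"],
        "compartment": ["plastid", "plastid", "plastid", "plastid", "plastid", "plastid", "plastid", "plastid", "plastid", "plastid", "plastid", "plastid", "plastid", "plastid", "nuclear", "nuclear", "nuclear", "nuclear", "nuclear", "nuclear", "nuclear", "nuclear", "nuclear", "nuclear"]
      }
    },
    {
      "name": "Photosystem I",
      "genes": {
        "gene":        ["psaA", "psaB", "psaC", "psaI", "psaJ", "psaD", "psaE", "psaF", "psaG", "psaH", "psaK", "psaL", "psaM", "psaN", "psaO", "psaP"],
        "compartment": ["plastid", "plastid", "plastid", "plastid", "plastid", "nuclear", "nuclear", "nuclear", "nuclear", "nuclear", "nuclear", "nuclear", "nuclear", "nuclear", "nuclear", "nuclear"]
      }
    },
    {
      "name": "Cytochrome b6/f complex",
      "genes": {
        "gene":        ["petA", "petG", "petN", "petC", "petM"],
        "compartment": ["plastid", "plastid", "plastid", "nuclear", "nuclear"]
      }
    },
    {
      "name": "Photosynthetic electron transport",
      "genes": {
        "gene":        ["petB", "petD", "petE", "petF", "petH", "petJ"],
        "compartment": ["plastid", "plastid", "nuclear", "nuclear", "nuclear", "nuclear"]
      }
    },
    {
      "name": "F-type ATPase",
      "genes": {
        "gene":        ["atpA", "atpB", "atpE", "atpF", "atpH", "atpI", "atpC", "atpD", "atpG", "atpO", "atpQ", "atpR"],
        "compartment": ["plastid", "plastid", "plastid", "plastid", "plastid", "plastid", "nuclear", "nuclear", "nuclear", "nuclear", "nuclear", "nuclear"]
      }
    }
  ],
  "aliases": {
    "alpha": "atpA",
    "beta": "atpB",
    "gamma": "atpC",
    "delta": "atpD",
    "epsilon": "atpE",
    "a": "atpI",
    "b": "atpF",
    "c": "atpH",
    "C": "atpC",
    "B": "atpF"
  }
}
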
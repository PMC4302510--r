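{
  "metabolites": ["A", "B", "C", "D"],
  "reactions": [
    {
      "id": "r1",
      "stoich": {
        "A": 1
      },
      "reversible": true
    },
    {
      "id": "r2",
      "stoich": {
        "A": -1,
        "B": 1,
        "C": 1
      },
      "reversible": false,
      "gpr": "gA"
    },
    {
      "id": "r3",
      "stoich": {
        "B": -1,
        "C": -1,
        "D": 1
      },
      "reversible": false,
      "gpr": "gA or gB"
    },
    {
      "id": "r4",
      "stoich": {
        "D": -1
      },
      "reversible": false
    },
    {
      "id": "r5",
      "stoich": {
        "C": 1
      },
      "reversible": false,
      "gpr": "gC"
    },
    {
      "id": "r6",
      "stoich": {
        "A": 1,
        "C": -1,
        "D": 1
      },
      "reversible": false,
      "gpr": "gC"
    }
  ],
  "genes": ["gA", "gB", "gC"]
}
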
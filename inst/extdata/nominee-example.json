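{
  "schema_version": "1.0",
  "nodes": [
    {
      "id": "PN",
      "role": "cue",
      "appeal": 0
    },
    {
      "id": "C1",
      "role": "alternative",
      "appeal": 0.8
    },
    {
      "id": "C2",
      "role": "alternative",
      "appeal": 0.3
    },
    {
      "id": "C3",
      "role": "alternative",
      "appeal": -0.4
    }
  ],
  "edges": [
    {
      "source": "C1",
      "target": "PN",
      "weight": 1
    },
    {
      "source": "C2",
      "target": "PN",
      "weight": 1
    },
    {
      "source": "C1",
      "target": "C2",
      "weight": -1.5
    },
    {
      "source": "C3",
      "target": "PN",
      "weight": 0.5
    }
  ],
  "beta": 1,
  "mu": 1
}
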
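{
  "schema_version": 1,
  "name": "chain_l2_m2",
  "states": [
    {
      "name": "0",
      "u": -0.2,
      "terminal": false
    },
    {
      "name": "1",
      "u": -0.2,
      "terminal": false
    },
    {
      "name": "2",
      "u": 1,
      "terminal": true
    }
  ],
  "transitions": [
    {
      "state": "0",
      "behaviour": "B1",
      "next": "1",
      "prob": 1
    },
    {
      "state": "0",
      "behaviour": "B2",
      "next": "0",
      "prob": 1
    },
    {
      "state": "1",
      "behaviour": "B1",
      "next": "2",
      "prob": 1
    },
    {
      "state": "1",
      "behaviour": "B2",
      "next": "0",
      "prob": 1
    }
  ],
  "entry": [
    {
      "state": "0",
      "prob": 1
    }
  ],
  "start": "0",
  "attempt_closure": "return",
  "meta": {
    "kind": "chain",
    "l": 2,
    "m": 2,
    "b": 1,
    "c": 0.2,
    "p": 0,
    "correct": {
      "0": "B1",
      "1": "B1"
    }
  },
  "agent": {
    "alpha_v": 0.1,
    "alpha_w": 0.1,
    "beta": 5,
    "chaining": true
  },
  "provenance": [
    "chain of l=2 steps, repertoire m=2 per state",
    "printed values: reward b=1, cost c=0.2; entry parameter p=0",
    "mistakes reset to state 0; defaults alpha=0.1, beta=5"
  ]
}
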
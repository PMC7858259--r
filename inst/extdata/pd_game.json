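{
  "agent_id": "Ego",
  "agents": {
    "ego": [
      "E1",
      "E2",
      "E3"
    ],
    "alter": [
      "A1",
      "A2",
      "A3"
    ]
  },
  "rewards": {
    "E1,A1": 3,
    "E1,A2": 3,
    "E1,A3": 0,
    "E2,A1": 3,
    "E2,A2": 3,
    "E2,A3": 0,
    "E3,A1": 5,
    "E3,A2": 5,
    "E3,A3": 1
  },
  "prior": {
    "E1,A1": 0.13043472589794528,
    "E1,A2": 0.13043472589794528,
    "E1,A3": 2.1739120982990875e-07,
    "E2,A1": 0.13043472589794528,
    "E2,A2": 0.13043472589794528,
    "E2,A3": 2.1739120982990875e-07,
    "E3,A1": 0.21739120982990878,
    "E3,A2": 0.21739120982990878,
    "E3,A3": 0.043478241965981754
  },
  "opponent_model": {
    "A1": 0.33333333333333331,
    "A2": 0.33333333333333331,
    "A3": 0.33333333333333331
  },
  "policies": [
    {
      "name": "Policy 1",
      "kind": "forced_action",
      "action": "E1"
    },
    {
      "name": "Policy 2",
      "kind": "forced_action",
      "action": "E2"
    },
    {
      "name": "Policy 3",
      "kind": "forced_action",
      "action": "E3"
    },
    {
      "name": "Cooperate",
      "kind": "contract",
      "banned_ego": [
        "E3"
      ],
      "banned_alter": [
        "A3"
      ]
    }
  ],
  "floor": 9.9999999999999995e-07
}
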
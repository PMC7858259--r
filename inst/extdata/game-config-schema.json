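{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "Two-agent game configuration",
  "type": "object",
  "required": ["agents", "rewards", "policies"],
  "properties": {
    "agent_id": {"type": "string", "default": "Ego"},
    "agents": {
      "type": "object",
      "required": ["ego", "alter"],
      "properties": {
        "ego": {"type": "array", "items": {"type": "string"}, "minItems": 1},
        "alter": {"type": "array", "items": {"type": "string"}, "minItems": 1}
      }
    },
    "rewards": {
      "type": "object",
      "description": "Non-negative utility per joint state, keyed '<ego_action>,<alter_action>'; every joint state must appear and at least one reward must be positive.",
      "additionalProperties": {"type": "number", "minimum": 0}
    },
    "prior": {
      "type": "object",
      "description": "Optional explicit preference prior (state -> probability, summing to 1); overrides the reward-derived prior.",
      "additionalProperties": {"type": "number", "minimum": 0}
    },
    "opponent_model": {
      "type": "object",
      "description": "Optional belief over the other agent's actions (alter action -> probability); uniform when omitted.",
      "additionalProperties": {"type": "number", "minimum": 0}
    },
    "policies": {
      "type": "array",
      "minItems": 1,
      "items": {
        "type": "object",
        "required": ["name", "kind"],
        "properties": {
          "name": {"type": "string"},
          "kind": {"enum": ["forced_action", "contract"]},
          "action": {"type": "string", "description": "forced_action only: the single ego action taken"},
          "banned_ego": {"type": "array", "items": {"type": "string"}},
          "banned_alter": {"type": "array", "items": {"type": "string"}}
        }
      }
    },
    "floor": {"type": "number", "minimum": 0, "default": 1e-6}
  }
}
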
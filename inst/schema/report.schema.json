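{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "r2slopes analysis report",
  "type": "object",
  "required": ["family", "method", "partition", "r2"],
  "properties": {
    "family": { "type": "string" },
    "method": { "type": "string" },
    "partition": {
      "type": "object",
      "required": ["sigma2_f", "sigma2_terms", "sigma2_e", "sigma2_d"],
      "properties": {
        "sigma2_f": { "type": "number", "minimum": 0 },
        "sigma2_terms": { "type": "object" },
        "sigma2_e": { "type": "number", "minimum": 0 },
        "sigma2_d": { "type": "number", "minimum": 0 }
      }
    },
    "r2": {
      "type": "object",
      "required": ["marginal", "conditional"],
      "properties": {
        "marginal": { "type": "number", "minimum": 0, "maximum": 1 },
        "conditional": { "type": "number", "minimum": 0, "maximum": 1 }
      }
    },
    "fit": {
      "type": "object",
      "required": ["loglik", "converged", "n_groups"],
      "properties": {
        "loglik": { "type": "number" },
        "method": { "type": "string" },
        "converged": { "type": "boolean" },
        "n_groups": { "type": "number", "minimum": 2 },
        "iterations": { "type": "number", "minimum": 1 }
      }
    }
  }
}
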
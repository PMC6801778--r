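{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "memanchor analysis report",
  "type": "object",
  "required": ["package", "version", "seed", "config_hash", "params", "systems"],
  "properties": {
    "package": {"const": "memanchor"},
    "version": {"type": "string"},
    "seed": {"type": "integer"},
    "config_hash": {"type": "string"},
    "params": {
      "type": "object",
      "properties": {
        "lag": {"type": "number", "description": "JDA lag, ns"},
        "local_cutoff": {"type": "number", "description": "local order radius, nm"},
        "neighbor_cutoff": {"type": "number", "description": "insertion-depth neighbour radius, nm"},
        "bin_width": {"type": "number", "description": "depth histogram bin, nm"},
        "n_blocks": {"type": "integer"}
      }
    },
    "systems": {
      "type": "object",
      "minProperties": 1,
      "additionalProperties": {
        "type": "object",
        "properties": {
          "membrane": {
            "type": "object",
            "required": ["thickness", "area_per_lipid", "units"],
            "properties": {
              "thickness": {"type": "number", "exclusiveMinimum": 0},
              "thickness_sd": {"type": ["number", "null"]},
              "area_per_lipid": {"type": "number", "exclusiveMinimum": 0},
              "area_per_lipid_sd": {"type": ["number", "null"]},
              "order": {"type": ["number", "null"]},
              "order_sd": {"type": ["number", "null"]},
              "units": {"type": "object"}
            }
          },
          "diffusion": {
            "type": "object",
            "required": ["table"],
            "properties": {
              "table": {
                "type": ["object", "array"],
                "description": "per-species D (JDA and MSD), 1e-7 cm^2/s, with sd"
              }
            }
          },
          "geometry": {
            "type": "object",
            "properties": {
              "depth_mean": {"type": "number"},
              "depth_sd": {"type": "number"},
              "depth_modality": {"type": "integer"},
              "theta_mean": {"type": "number"},
              "omega_mean": {"type": "number"},
              "rgyr_mean": {"type": "number"},
              "units": {"type": "object"}
            }
          }
        }
      }
    }
  }
}
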
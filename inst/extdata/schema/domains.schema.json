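{
  "$id": "phylotracks-domains/1",
  "type": "object",
  "required": ["schema", "parameters", "tree", "leaves", "alignment", "features"],
  "properties": {
    "schema": {"type": "string", "enum": ["phylotracks-domains/1"]},
    "parameters": {
      "type": "object",
      "required": ["mode", "evalue_max", "overlap_fraction_max", "tree_backend"],
      "properties": {
        "mode": {"type": "string", "enum": ["full", "partial"]},
        "evalue_max": {"type": "number"},
        "overlap_fraction_max": {"type": "number"},
        "tree_backend": {"type": "string"},
        "aligner_backend": {"type": "string"},
        "kmer_size": {"type": "integer"},
        "enumerate_leaves": {"type": "boolean"},
        "skip_features": {"type": "boolean"},
        "two_area": {"type": "boolean"}
      }
    },
    "tree": {"type": "string"},
    "leaves": {"type": "array", "items": {"type": "string"}},
    "alignment": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["id", "residues"],
        "properties": {
          "id": {"type": "string"},
          "residues": {"type": "string"}
        }
      }
    },
    "features": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["protein_id", "features"],
        "properties": {
          "protein_id": {"type": "string"},
          "features": {
            "type": "array",
            "items": {
              "type": "object",
              "required": ["kind", "accession", "name", "start", "end"],
              "properties": {
                "kind": {"type": "string", "enum": ["domain", "transmembrane", "low_complexity"]},
                "source": {"type": "string"},
                "accession": {"type": "string"},
                "name": {"type": "string"},
                "start": {"type": "integer"},
                "end": {"type": "integer"},
                "bit_score": {"type": ["number", "null"]},
                "evalue": {"type": ["number", "null"]}
              }
            }
          }
        }
      }
    }
  }
}
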
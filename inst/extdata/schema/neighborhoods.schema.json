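{
  "$id": "phylotracks-neighborhoods/1",
  "type": "object",
  "required": ["schema", "parameters", "tree", "tree_source", "queries", "clusters", "operons"],
  "properties": {
    "schema": {"type": "string", "enum": ["phylotracks-neighborhoods/1"]},
    "parameters": {
      "type": "object",
      "required": ["window", "nonshared_max", "operon_gap_max", "require_same_strand"],
      "properties": {
        "window": {"type": "integer"},
        "nonshared_max": {"type": "integer"},
        "operon_gap_max": {"type": "integer"},
        "require_same_strand": {"type": "boolean"},
        "evalue_max": {"type": "number"},
        "overlap_fraction_max": {"type": "number"}
      }
    },
    "tree": {"type": "string"},
    "tree_source": {"type": "string"},
    "queries": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["leaf", "query_gene_id", "genes"],
        "properties": {
          "leaf": {"type": "string"},
          "query_gene_id": {"type": "string"},
          "truncated_left": {"type": "boolean"},
          "truncated_right": {"type": "boolean"},
          "wrapped": {"type": "boolean"},
          "genes": {
            "type": "array",
            "items": {
              "type": "object",
              "required": ["gene_id", "replicon_id", "start", "end", "strand", "is_query"],
              "properties": {
                "gene_id": {"type": "string"},
                "locus_tag": {"type": ["string", "null"]},
                "protein_id": {"type": ["string", "null"]},
                "replicon_id": {"type": "string"},
                "start": {"type": "integer"},
                "end": {"type": "integer"},
                "strand": {"type": "string", "enum": ["+", "-"]},
                "product": {"type": ["string", "null"]},
                "is_query": {"type": "boolean"},
                "cluster_id": {"type": ["integer", "null"]},
                "operon_id": {"type": ["integer", "null"]},
                "domain_accessions": {"type": "array", "items": {"type": "string"}}
              }
            }
          }
        }
      }
    },
    "clusters": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["gene_id"],
        "properties": {
          "gene_id": {"type": "string"},
          "cluster_id": {"type": ["integer", "null"]}
        }
      }
    },
    "operons": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["operon_id", "replicon_id", "strand", "gene_id", "position"],
        "properties": {
          "operon_id": {"type": "integer"},
          "replicon_id": {"type": "string"},
          "strand": {"type": "string", "enum": ["+", "-"]},
          "gene_id": {"type": "string"},
          "position": {"type": "integer"}
        }
      }
    }
  }
}
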
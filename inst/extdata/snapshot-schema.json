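{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "targetrank snapshot",
  "description": "Offline bundle of pathway membership, gene identifier maps, per-target attributes and drug links consumed by the targetrank pipeline. Canonical serialization: object keys sorted; pathways/targets keyed by accession; gene_map ordered by ensembl_id; drugs ordered by (drug_id, target_ensembl_id).",
  "type": "object",
  "required": ["schema_version", "pathways", "gene_map", "targets", "drugs"],
  "properties": {
    "schema_version": {"type": "string"},
    "pathways": {
      "type": "object",
      "additionalProperties": {
        "type": "object",
        "required": ["name", "source_db", "member_ensembl_ids"],
        "properties": {
          "name": {"type": "string", "minLength": 1},
          "source_db": {"enum": ["KEGG", "Reactome", "PID", "BioCarta", "Panther", "other"]},
          "member_ensembl_ids": {
            "type": "array",
            "items": {"type": "string", "pattern": "^ENSG[0-9]{11}$"}
          }
        }
      }
    },
    "gene_map": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["symbol", "ensembl_id"],
        "properties": {
          "symbol": {"type": "string"},
          "ensembl_id": {"type": "string", "pattern": "^ENSG[0-9]{11}$"},
          "entrez_id": {"type": ["integer", "null"]},
          "uniprot_ids": {"type": "array", "items": {"type": "string"}}
        }
      }
    },
    "targets": {
      "type": "object",
      "additionalProperties": {
        "type": "object",
        "required": [
          "symbol", "name", "n_associated_diseases", "tractability_count",
          "n_safety_liabilities", "n_unique_drugs", "n_approved",
          "n_phase1", "n_phase2", "n_phase3", "n_phase4"
        ],
        "properties": {
          "symbol": {"type": "string"},
          "name": {"type": "string"},
          "uniprot_ids": {"type": "array", "items": {"type": "string"}},
          "n_associated_diseases": {"type": "integer", "minimum": 0},
          "tractability_count": {"type": "integer", "minimum": 0},
          "tractability_flags": {
            "type": ["object", "null"],
            "minProperties": 12,
            "maxProperties": 12,
            "propertyNames": {
              "enum": [
                "sm_approved", "sm_advanced_trial", "sm_phase1",
                "ab_approved", "ab_advanced_trial", "ab_phase1",
                "pr_approved", "pr_advanced_trial", "pr_phase1",
                "oc_approved", "oc_advanced_trial", "oc_phase1"
              ]
            },
            "additionalProperties": {"type": "boolean"}
          },
          "subcellular_location": {"type": ["string", "null"]},
          "n_safety_liabilities": {"type": "integer", "minimum": 0},
          "n_unique_drugs": {"type": "integer", "minimum": 0},
          "n_approved": {"type": "integer", "minimum": 0},
          "n_phase1": {"type": "integer", "minimum": 0},
          "n_phase2": {"type": "integer", "minimum": 0},
          "n_phase3": {"type": "integer", "minimum": 0},
          "n_phase4": {"type": "integer", "minimum": 0}
        }
      }
    },
    "drugs": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["drug_id", "max_phase", "is_approved", "target_ensembl_id"],
        "properties": {
          "drug_id": {"type": "string"},
          "drug_name": {"type": "string"},
          "drug_type": {"type": "string"},
          "action": {"type": "string"},
          "max_phase": {"type": "integer", "minimum": 0, "maximum": 4},
          "is_approved": {"type": "boolean"},
          "target_ensembl_id": {"type": "string", "pattern": "^ENSG[0-9]{11}$"}
        }
      }
    }
  }
}
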
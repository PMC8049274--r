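{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "Metagenome binning report",
  "type": "object",
  "required": ["input", "totals", "bins"],
  "properties": {
    "input": {
      "type": "object",
      "required": ["contigs_in", "contigs_after_qc"],
      "properties": {
        "contigs_file": { "type": ["string", "null"] },
        "contigs_in": { "type": "integer", "minimum": 0 },
        "contigs_after_qc": { "type": "integer", "minimum": 0 }
      }
    },
    "totals": {
      "type": "object",
      "required": ["bins", "good", "poor", "binned_contigs", "unbinned_contigs"],
      "properties": {
        "bins": { "type": "integer", "minimum": 0 },
        "good": { "type": "integer", "minimum": 0 },
        "poor": { "type": "integer", "minimum": 0 },
        "binned_contigs": { "type": "integer", "minimum": 0 },
        "unbinned_contigs": { "type": "integer", "minimum": 0 }
      }
    },
    "bins": {
      "type": "array",
      "items": {
        "type": "object",
        "required": [
          "bin_id", "organism", "reference_genome_ids", "species_id",
          "seed_similarity", "score", "coarse_consistency",
          "fine_consistency", "completeness", "contamination",
          "seed_count", "seed_length_ok", "contig_count", "dna_size",
          "n50", "mean_coverage", "verdict", "failing"
        ],
        "properties": {
          "bin_id": { "type": "string" },
          "organism": { "type": "string" },
          "reference_genome_ids": {
            "type": "array",
            "items": { "type": "string" },
            "minItems": 1
          },
          "species_id": { "type": "string" },
          "seed_similarity": { "type": "number", "minimum": 0, "maximum": 1 },
          "score": { "type": "number", "minimum": 0, "maximum": 100 },
          "coarse_consistency": { "type": "number", "minimum": 0, "maximum": 100 },
          "fine_consistency": { "type": "number", "minimum": 0, "maximum": 100 },
          "completeness": { "type": "number", "minimum": 0, "maximum": 100 },
          "contamination": { "type": "number", "minimum": 0, "maximum": 100 },
          "seed_count": { "type": "integer", "minimum": 0 },
          "seed_length_ok": { "type": "boolean" },
          "contig_count": { "type": "integer", "minimum": 1 },
          "dna_size": { "type": "number", "minimum": 0 },
          "n50": { "type": "number", "minimum": 0 },
          "mean_coverage": { "type": "number", "minimum": 0 },
          "verdict": { "enum": ["good", "poor"] },
          "failing": {
            "type": "array",
            "items": {
              "enum": ["contamination", "fine_consistency", "completeness", "seed"]
            }
          }
        }
      }
    }
  }
}
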
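{
  "seed": 42,
  "causal_gene": "G01",
  "causal_variant_id": "1:1001:C:T",
  "causal_rsid": "rs1000001",
  "decoy_variant_ids": "2:1002:G:A",
  "planted_de_genes": ["G01", "G11", "G12", "G13"],
  "planted_log2fc": {
    "G01": -2,
    "G11": 2.5,
    "G12": -2.2,
    "G13": 1.8
  },
  "anchor_pathways": ["PWA", "PWB"],
  "expected_edge": {
    "pathway_a": "PWA",
    "pathway_b": "PWB",
    "shared_genes": ["G01", "G12"],
    "jc": 0.5,
    "oc": 0.666666666666667
  }
}
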
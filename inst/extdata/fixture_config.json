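{
  "seed": 101,
  "stages": ["simulate", "de", "locus", "ptr", "enrich"],
  "grouping": "tumor_vs_normal",
  "n_sim": 500,
  "universe": "utr",
  "sim": {
    "n_mirnas": 60,
    "n_genes": 2000,
    "n_tumor": 12,
    "n_normal": 8,
    "n_batches": 2,
    "dispersion": 0.05,
    "planted_up_mirnas": {
      "mir_0001": 2.5, "mir_0002": 2.0, "mir_0003": 3.0,
      "mir_0004": 2.0, "mir_0005": 2.5, "mir_0006": 2.0
    },
    "planted_down_mirnas": {
      "mir_0007": -2.0, "mir_0008": -2.5, "mir_0009": -2.0, "mir_0010": -3.0
    },
    "planted_gpr": {"n": 120, "start": 1, "log2fc": -2},
    "planted_lpr": {"n": 60, "start": 121, "log2fc": 2},
    "planted_transcriptional": {"n": 60, "start": 181, "log2fc": 1.5},
    "master_mirna": "mir_0001",
    "site_enrichment_odds": 3,
    "baseline_site_rate": 0.5
  }
}
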
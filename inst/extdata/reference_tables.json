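{
  "comment": "Published reference statistics from the genome-wide mitosis RNAi screen conservation study: 2x2 contingency tables (MH conserved, MH non-conserved, other conserved, other non-conserved) at the 70% inter-species conservation cutoff with their printed one-sided Fisher p-values, and giant-component-size Z-test triples (observed, resampling-null mean, sd) with their printed one-sided p-values. 'digits' is the number of significant digits the source printed.",
  "fisher": [
    {"id": "fisher_all_genes_homologene", "counts": [398, 165, 11170, 6533], "printed": 1e-04, "digits": 1},
    {"id": "fisher_all_edges_kegg", "counts": [778, 1261, 9952, 21164], "printed": 6.93e-09, "digits": 3},
    {"id": "fisher_all_edges_reactome", "counts": [2128, 6754, 10614, 53900], "printed": 4.54e-64, "digits": 3},
    {"id": "fisher_min_genes_homologene", "counts": [398, 165, 1804, 592], "printed": 0.989, "digits": 3},
    {"id": "fisher_min_edges_kegg", "counts": [675, 1124, 8654, 16418], "printed": 0.0054, "digits": 2},
    {"id": "fisher_min_edges_reactome", "counts": [745, 2252, 2057, 7070], "printed": 0.005, "digits": 1},
    {"id": "fisher_regulatory_genes_homologene", "counts": [398, 165, 915, 378], "printed": 0.536, "digits": 3},
    {"id": "fisher_regulatory_edges_kegg", "counts": [480, 796, 2970, 7129], "printed": 2.06e-09, "digits": 3},
    {"id": "fisher_regulatory_edges_reactome", "counts": [519, 1824, 1284, 5469], "printed": 6e-04, "digits": 1}
  ],
  "ztest": [
    {"id": "ztest_min_gene_removal", "observed": 1383, "null_mean": 1388.3, "null_sd": 13.95, "printed": 0.35, "digits": 2},
    {"id": "ztest_regulatory_gene_removal", "observed": 628, "null_mean": 623.1, "null_sd": 8.8, "printed": 0.71, "digits": 2}
  ]
}
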
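{
  "table2_cohort": {
    "files": ["table2_expression.tsv", "table2_subjects.tsv"],
    "description": "Self-collected plasma qPCR cohort: 6 genes x 50 subjects (32 sepsis of which 11 septic shock, 18 healthy controls); relative copy counts on the identity scale."
  },
  "table4_panels": {
    "files": ["table4_panels.json"],
    "description": "Published max-logistic competing-factor classifiers for 11 cohorts plus three disease-progression comparisons, with their reported accuracy/sensitivity/specificity."
  },
  "table1_meta": {
    "files": ["table1_meta.tsv"],
    "description": "Cohort metadata for the 12 datasets (accession, tissue, population, case/control sizes)."
  },
  "pbmc_panels": {
    "files": ["pbmc_panels.json"],
    "description": "PBMC-cohort classifiers on the LN(x+1) expression scale."
  }
}
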
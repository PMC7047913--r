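# Bundled example data

- `synthetic_cox1_alignment.txt` — a **synthetic** codon-level alignment in
  the package's three-lines-per-species dialect (header, amino-acid row,
  space-separated codon row per species). It was produced by the package's
  own simulator (`simulate_dataset()`, 240 codon columns, seed 2026) with an
  ATA Met-to-Ile reassignment planted in the three-species
  `app_olongicauda`/`app_bstygius`/`app_merythro` clade, and the coding
  sequences threaded under their ascidian-code (table 13) translations.
  It contains no biological sequence data; it exists so the file reader and
  the conserved-column tabulation can be exercised on a stable on-disk input.
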
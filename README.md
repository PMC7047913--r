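# mitocode

Alignment-based assessment of mitochondrial genetic codes: which translation
table does a lineage actually use, and is there evidence for further codon
reassignments?

## The problem

Animal mitochondria repeatedly rewire their genetic code. The AGR codon pair
(AGA/AGG) is a stop in the vertebrate mitochondrial code (NCBI table 2),
serine in the invertebrate code (table 5) and glycine in the ascidian code
(table 13); table 9 (echinoderm) keeps ATA as Ile where tables 2/5/13 read
Met. For poorly sampled lineages — tunicates outside the ascidians being the
motivating case — repositories may apply the wrong table, silently turning
conserved glycines into serines or truncating open reading frames.

When tRNA evidence is unavailable, the code must be inferred from coding
sequences themselves. `mitocode` implements the comparative argument as a
reusable pipeline:

1. extract gene regions from contigs (GenBank-style `ACC[START:END]`
   coordinates, reverse strand when start > end, optional circular wrap) and
   build majority consensi / haplotype groups from pre-aligned EST fragments;
2. translate under alternative frozen translation tables (1, 2, 5, 9, 13),
   scan for in-frame stops, and diff codes codon by codon;
3. thread each coding sequence's codons under a protein multiple alignment
   (`---` under gaps, per-cell translation consistency enforced);
4. tabulate, for a focal species and codon family (ATA/ATC/ATG/ATT or
   TGA/TGG), how often each codon occurs at columns where the *other*
   species conserve each context amino acid. A column is "conserved" for an
   amino acid when all voting units carry it except at most `max_mismatch`
   (default 1); sister species can be grouped into a single voting unit and
   are excluded together with the focal species;
5. turn the tables into reassignment calls: *support* counts the focal codon
   at columns conserved for the candidate amino acid, *conflict* at columns
   conserved for the current assignment. A call is `suggested` only when
   support ≥ `min_support` (default 2) and conflict is zero, and gets a
   small-parsimony note (minimum number of origins on a supplied tree, root
   constrained to absence);
6. validate everything end to end with a seeded simulator of indel-free
   gene families along a phylogeny with lineage-specific planted codes and
   full ground truth.

## Worked example

The package ships a small **synthetic** codon-level alignment (written by
its own simulator; see `inst/extdata/README.md`) with an ATA Met→Ile
reassignment planted in a three-species clade containing the grouped sister
pair `app_olongicauda`/`app_bstygius`.

```r
library(mitocode)

get_code(13)
#> Genetic code table 13 - ascidian mitochondrial
#>   differs from standard code at: AGA (R->G), AGG (R->G), ATA (I->M), TGA (*->W)

translate_cds("TTAGCTAGAGGTTGA", get_code(5))   # invertebrate: AGA = Ser
#> [1] "LASGW"
translate_cds("TTAGCTAGAGGTTGA", get_code(13))  # ascidian: AGA = Gly
#> [1] "LAGGW"
stop_scan("TTAGCTAGAGGTTGA", get_code(2))       # vertebrate: AGA = stop
#> [1] 3

aln <- read_codon_alignment(system.file("extdata",
  "synthetic_cox1_alignment.txt", package = "mitocode"))
rule <- conservation_rule(max_mismatch = 1,
                          focal_groups = list(sim_focal_pair()))

codon_context_table(aln, "app_olongicauda",
                    c("ATA", "ATC", "ATG", "ATT"), c("M", "I"),
                    rule, gene = "cox1-like")
#> Codon context table (cox1-like) - focal: app_olongicauda
#>               row app_olongicauda
#> 1      ATA number              10
#> ...
#> 5  ATA on cons. M               0
#> 6  ATA on cons. I               4
```

The focal species uses ATA ten times; four of those sit at columns where the
remaining species conserve isoleucine, and none where methionine is
conserved — the signature of ATA encoding Ile in this lineage. Pooling the
three clade members and annotating with the tree:

```r
calls <- clade_calls(aln, sim_focal_clade(), get_code(13), rule,
                     list(ATN = c("ATA", "ATC", "ATG", "ATT")),
                     list(ATN = c("M", "I")))
parsimony_note(calls[calls$verdict == "suggested", ], sim_study_tree())
#>                            species_or_clade codon from_aa to_aa support conflict gains
#> 1 app_bstygius+app_merythro+app_olongicauda   ATA       M     I      11        0     1
```

Eleven concordant conserved columns across the clade, zero conflicting ones,
and a single origin on the tree: the planted reassignment, recovered.

`run_pipeline()` drives the same steps from a YAML/list configuration and
writes a report bundle (wide per-family tables, `calls.tsv`/`calls.json`, a
run log with parameters and input checksums); `exec/mitocode` wraps the main
functions as shell subcommands (`codes`, `extract`, `consensus`, `thread`,
`transpose`, `table`, `infer`, `simulate`, `run`).

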
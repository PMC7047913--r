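---
title: "Assessing mitochondrial genetic codes from codon-level alignments"
author: "mitocode"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing mitochondrial genetic codes from codon-level alignments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitocode)
```

## The problem

Animal mitochondrial genomes occasionally reassign codons: the codon pair
AGA/AGG ("AGR") is a stop in the vertebrate mitochondrial code (NCBI table
2), serine in the invertebrate code (table 5), and glycine in the ascidian
code (table 13); the echinoderm code (table 9) keeps ATA as isoleucine where
tables 2/5/13 read methionine. Which code a poorly sampled lineage uses
matters in practice — a repository translating a tunicate gene with the
invertebrate table will print serines at functionally conserved glycines —
and choosing wrongly can corrupt downstream phylogenetics.

Direct evidence for a reassignment (a tRNA with a matching anticodon change)
is often out of reach when only fragments of draft genomes or EST consensi
exist. `mitocode` implements the indirect, alignment-based argument:
translate candidate genes under a reference code, thread the codons back
under a protein multiple-sequence alignment, and ask which amino acid the
*other* species carry at the columns where a focal species uses a focal
codon. If a species' ATA codons sit systematically at columns where everyone
else has a conserved isoleucine — and never where methionine is conserved —
the parsimonious reading is that ATA encodes Ile in that lineage.

## The procedure

1. **Sequence preparation** (`extract_region`, `majority_consensus`,
   `group_haplotypes`). Gene regions are cut from contigs with GenBank-style
   1-based inclusive coordinates; `start > end` denotes the reverse strand,
   and contigs can be flagged circular so regions may wrap the origin.
   EST-like fragment sets, already aligned, are collapsed to a majority
   consensus per column (ties broken by the fixed order A < C < G < T < N and
   flagged), and can be partitioned into haplotypes: fragments group together
   exactly when they agree at every variable column where both have coverage,
   closed transitively. The haplotype rule is this package's formalisation of
   what is usually done by eye; single-linkage closure is the weakest rule
   consistent with "no observed disagreement".

2. **Translation** (`get_code`, `translate_cds`, `stop_scan`). Translation
   tables 1, 2, 5, 9 and 13 are frozen in the package so results cannot
   drift with an external resource. Codons containing any non-ACGT symbol
   (ambiguity codes from EST consensi) translate to `X` rather than raising
   an error, and a trailing partial codon is dropped silently — partial genes
   are the normal case here. Stops are emitted as `*`.

3. **Codon threading** (`thread_codons`). The protein MSA is an *input*:
   any aligner can produce it, and the bespoke computation starts after
   alignment. Threading places each coding sequence's codons under the
   corresponding residues, inserts `---` under alignment gaps, and enforces
   two invariants — the codon count must equal the residue count, and each
   codon must translate (under that species' code) to the residue above it,
   with a protein `X` accepting anything. Violations are errors that name
   the species and column; they are the earliest point at which a wrong code
   assumption becomes visible. A simulated or pre-trimmed indel-free family
   can skip the external aligner entirely via `codon_alignment_from_cds`.

4. **Conservation rule** (`conservation_rule`, `conserved_for`). A column is
   conserved for amino acid *a*, from the point of view of a focal species,
   when all voting units carry *a* except at most `max_mismatch` of them.
   The focal species never votes. Species can be declared a *focal group*
   (e.g. a sister pair): a group votes as one unit, and when the focal
   species belongs to a group the whole group is excluded by default
   (`partner_votes = FALSE`), so a sister species never corroborates its own
   pair. Defaults: `max_mismatch = 1` (the relaxed rule; 0 is strict
   identity), gaps and `X` excluded from voting
   (`count_gaps_as_mismatch = FALSE`).

   Two boundary decisions are ours because no published convention exists:
   (i) with few voting units more than one amino acid can satisfy the
   mismatch budget; `conserved_for` returns an amino acid only when it is
   the *unique* candidate, otherwise nothing — deterministic and
   conservative; (ii) a stop (`*`) can vote (it is a real translation state
   that legitimately breaks conservation) but is never returned as the
   conserved residue.

5. **Context tables** (`codon_context_table`, `context_tables_wide`). For a
   focal species and a codon family (ATA/ATC/ATG/ATT, or TGA/TGG), the table
   holds each codon's total count over the aligned region and its count at
   columns conserved for each context amino acid (Met/Ile, or Trp/Arg).
   Totals are computed over the aligned region only, so counts are
   well-defined for trimmed alignments. `shared_conserved_codon_columns`
   supports the complementary whole-clade question: columns conserved across
   *all* species where at least one species uses a focal codon (e.g. AGR at
   conserved glycines).

6. **Inference** (`infer_reassignments`, `clade_calls`). For each codon and
   each context amino acid differing from the codon's current assignment,
   *support* (count at columns conserved for the candidate) and *conflict*
   (count at columns conserved for the current assignment) are summed across
   tables — across genes, and across clade members when calling at clade
   level. A call is `suggested` only if support ≥ `min_support` **and**
   conflict is zero; positive support below the threshold is `insufficient`.
   The default `min_support = 2` encodes the qualitative practice of
   treating a single instance as anecdotal while two or more concordant
   conserved columns are worth reporting; it is deliberately a tunable
   parameter, not a significance test — with counts this small a formal test
   would suggest precision the data cannot support. Calls between
   biochemically similar residues (Ile/Met, Lys/Arg, ...) carry a caution
   note, since substitution alone can mimic a code change there.

7. **Parsimony note** (`parsimony_note`, `min_reassignment_gains`). Each
   call is annotated with the minimum number of branches on which the
   reassignment must arise on a supplied rooted tree — small-parsimony
   change counting on a binary presence/absence character, computed by
   dynamic programming over states (so multifurcations are handled), with
   the root constrained to absence. The root constraint treats the
   reassignment as derived: a character present in every leaf still needs at
   least one origin, which matches the question being asked ("how many
   independent changes of the code?"); unconstrained Fitch counting would
   report zero there.

## The simulator and what passing tests mean

`simulate_dataset` generates indel-free orthologous families with full
ground truth so the whole pipeline can be validated without downloads.
Amino acids start from a uniform-random root sequence; a configurable
fraction of columns (`invariant_fraction`, default 0.4) is frozen, and the
rest evolve by a Poisson process of uniform replacements (rate =
`substitution_rate` × branch length). Codons are then drawn per species
from the synonymous codons of that species' (possibly planted) code,
proportionally to codon-usage weights, with the focal codons AGA/AGG/ATA/TGA
boosted (×3 by default) so the codons under study are well represented.
Everything is driven by one seed; identical configurations give
bit-identical datasets.

The default tree has 12 tips mirroring the structure the analysis exploits:
three outgroups, three ascidian-like and two thaliacean-like tips, and four
appendicularian-like tips of which three form a focal clade containing a
grouped sister pair. Voter-side branch lengths (1.1–1.8 expected
substitutions per variable site root-to-tip) model deeply diverged
mitochondrial proteins: variable columns are near saturation, so column
conservation is carried almost entirely by the invariant fraction. This is
deliberate. With shallow divergence a variable column can look conserved
merely because no voter happened to change, and a single focal-lineage
Met→Ile substitution over such a column produces spurious "conflict"; at
realistic inter-phylum depths that coincidence is vanishingly rare (0
failures in a 500-replicate stress run), which is also the regime the real
alignments of deeply conserved mitochondrial genes are in.

The simulator's deliberate non-realisms: uniform amino-acid replacement (no
empirical exchangeability matrix, no rate heterogeneity beyond
invariant/variable), no indels, no mutational strand bias, no saturation at
the nucleotide level. Passing recovery tests therefore demonstrates that the
counting logic is correct and well-calibrated under clean conditions — not
that the method is robust to alignment error, frameshifts or RNA editing,
which are out of scope throughout.

Validation sizes used by the test-suite and the acceptance script: 20
replicates of 12 taxa × 500 codon columns for planted-truth recovery (one
ATA Met→Ile reassignment in the 3-taxon clade, `min_support = 2`), and a
matched null without any planted change, which must yield zero suggested
calls; exhaustive-enumeration oracles cover every 5-unit vote pattern for
the conservation rule and every rooted topology with up to 5 leaves (plus
sampled 6-leaf topologies) for the parsimony count.

## Numerical and formatting choices

* All user-facing coordinates and column indices are 1-based inclusive, the
  GenBank and R convention; `stop_scan` reports 1-based codon positions.
* Consensus ties and difference-to-consensus ties break by fixed documented
  symbol orders, so outputs are reproducible byte-for-byte.
* The interleaved "three lines per species" text format written by
  `write_codon_alignment` (header, amino-acid row, space-separated codon
  row) is this package's documented dialect; `read_codon_alignment` accepts
  it, and `transpose_columns`/`write_column_tsv` provide the per-column
  tabular view. Round-tripping is exact and tested.
* `run_pipeline` stages its outputs and moves them into place only on
  success; the run log records every effective parameter and input MD5, so
  a bundle is reproducible from its log.

## Known limitations

* The method detects *candidate* reassignments; confirmation requires tRNA
  evidence, which is explicitly out of scope.
* Counts at conserved columns are small by nature; `min_support` trades
  sensitivity against anecdote, and calls between substitutable residues
  (Ile/Met in particular) remain ambiguous evidence however many columns
  support them.
* The conservation rule treats voting units symmetrically; it does not
  weight by phylogenetic distance. Declaring focal groups is the only
  mechanism for discounting non-independence, and choosing those groups is
  the user's responsibility.
* Frameshifts, introns and RNA editing within genes are not modelled;
  threading will (correctly) refuse such sequences.
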
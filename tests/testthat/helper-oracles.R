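# Independent brute-force oracles and small fixture builders. These
# deliberately avoid the package's own code paths wherever they are used to
# check one.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
          "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

ALL_CODONS <- as.vector(outer(
  as.vector(outer(c("T", "C", "A", "G"), c("T", "C", "A", "G"), paste0)),
  c("T", "C", "A", "G"), paste0))

# naive per-character complement, independent of Biostrings
naive_revcomp <- function(seq) {
  comp <- c(A = "T", T = "A", G = "C", C = "G", R = "Y", Y = "R", S = "S",
            W = "W", K = "M", M = "K", B = "V", V = "B", D = "H", H = "D",
            N = "N")
  paste(rev(comp[strsplit(toupper(seq), "")[[1]]]), collapse = "")
}

# conservation decision recomputed directly from a vector of voting-unit
# states (amino acid, "-" for gap/unknown, "!" for internal disagreement)
oracle_conserved <- function(states, max_mismatch, count_gaps) {
  voting <- character(0)
  for (s in states) if (s != "-" || count_gaps) voting <- c(voting, s)
  cands <- character(0)
  for (a in unique(voting)) {
    if (!a %in% AA20) next
    bad <- 0L
    for (v in voting) if (v != a) bad <- bad + 1L
    if (bad <= max_mismatch) cands <- c(cands, a)
  }
  if (length(cands) == 1L) cands else NA_character_
}

# unit state of a set of residues, recomputed independently
oracle_unit_state <- function(v) {
  v <- v[!v %in% c("-", "X")]
  if (length(v) == 0L) return("-")
  if (length(unique(v)) == 1L) v[1] else "!"
}

# minimum change count with root fixed at absence, by enumerating every
# internal-node state assignment
brute_min_changes <- function(tree, present_tips) {
  ntip <- length(tree$tip.label)
  nint <- tree$Nnode
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])
  tip_states <- as.integer(tree$tip.label %in% present_tips)
  grid <- as.matrix(expand.grid(rep(list(0:1), nint)))
  grid <- grid[grid[, root - ntip] == 0L, , drop = FALSE]
  best <- Inf
  for (r in seq_len(nrow(grid))) {
    st <- c(tip_states, grid[r, ])
    best <- min(best, sum(st[tree$edge[, 1]] != st[tree$edge[, 2]]))
  }
  as.integer(best)
}

# build a codon_alignment directly from an amino-acid matrix and codon
# matrix (bypassing thread_codons) for planted-count tests
make_alignment <- function(aa_rows, codon_rows) {
  species <- names(aa_rows)
  df <- do.call(rbind, lapply(seq_along(aa_rows), function(i) {
    aa <- strsplit(aa_rows[[i]], "")[[1]]
    data.frame(column = seq_along(aa), species = species[i], aa = aa,
               codon = codon_rows[[i]], stringsAsFactors = FALSE)
  }))
  rebuild_alignment(df)
}

# random DNA of length n (multiple of 3 when codons = TRUE)
random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")

# build a codon_context_table object directly from given counts, for using
# published table cells as inference inputs
make_context_table <- function(focal, gene, family, contexts, totals, ctx) {
  structure(list(focal = focal, gene = gene, family = family,
                 contexts = contexts,
                 totals = setNames(as.integer(totals), family),
                 context_counts = matrix(as.integer(ctx), nrow = length(family),
                                         dimnames = list(family, contexts),
                                         byrow = TRUE),
                 rule = conservation_rule(1)),
            class = "codon_context_table")
}
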
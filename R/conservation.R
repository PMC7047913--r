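# The mismatch-tolerant conservation rule and the conserved-column codon
# usage tables (codon counts in a focal species, split by which amino acid
# the remaining species agree on).

#' Define a conservation rule
#'
#' A column is "conserved" for an amino acid when all voting units carry that
#' amino acid except at most \code{max_mismatch} of them
#' (\code{max_mismatch = 0} is strict identity; 1 is the relaxed rule that
#' tolerates a single deviating sequence). Species listed together in a
#' \code{focal_groups} entry are collapsed into a single voting unit: the
#' unit votes its members' shared residue, and disagreement inside the unit
#' makes it a mismatching unit. This is how closely related sister species
#' are prevented from counting as independent evidence.
#'
#' @param max_mismatch Non-negative integer; voting units allowed to deviate.
#' @param focal_groups List of character vectors of species ids; groups must
#'   be disjoint.
#' @param count_gaps_as_mismatch Logical. If \code{FALSE} (default) gap (and
#'   \code{"X"}) entries are excluded from voting; if \code{TRUE} they count
#'   as mismatching units.
#' @param partner_votes Logical. When the focal species belongs to a group,
#'   should the remaining group members still vote? Default \code{FALSE}:
#'   the whole group is excluded together with the focal species, so a
#'   sister species never corroborates its own pair.
#' @return Object of class \code{conservation_rule}.
#' @export
conservation_rule <- function(max_mismatch = 1L, focal_groups = list(),
                              count_gaps_as_mismatch = FALSE,
                              partner_votes = FALSE) {
  stopifnot(max_mismatch >= 0L)
  all_members <- unlist(focal_groups)
  if (anyDuplicated(all_members))
    stop("focal_groups must be disjoint")
  structure(list(max_mismatch = as.integer(max_mismatch),
                 focal_groups = focal_groups,
                 count_gaps_as_mismatch = isTRUE(count_gaps_as_mismatch),
                 partner_votes = isTRUE(partner_votes)),
            class = "conservation_rule")
}

# state of one voting unit: an amino-acid symbol, "-" (no usable residue),
# or "!" (internal disagreement). "X" is treated as unknown, like a gap.
.unit_state <- function(v) {
  v <- v[!(v %in% c("-", "X"))]
  if (!length(v)) return("-")
  u <- unique(v)
  if (length(u) == 1L) u else "!"
}

# collapse a named amino-acid column into voting-unit states, excluding
# `exclude` species; grouped species form one unit each.
.vote_states <- function(aa_col, exclude, rule) {
  use <- setdiff(names(aa_col), exclude)
  states <- character(0)
  taken <- character(0)
  for (g in rule$focal_groups) {
    mem <- intersect(use, g)
    if (length(mem)) {
      states <- c(states, .unit_state(aa_col[mem]))
      taken <- c(taken, mem)
    }
  }
  singles <- setdiff(use, taken)
  c(states, vapply(singles, function(s) .unit_state(aa_col[s]), character(1)))
}

# decide conservation from unit states under a rule; NA when no amino acid
# is the unique one held by all units except at most max_mismatch.
.conserved_from_states <- function(states, rule) {
  voting <- if (rule$count_gaps_as_mismatch) states else states[states != "-"]
  syms <- unique(voting[voting %in% .AA_SYMBOLS])
  if (!length(syms)) return(NA_character_)
  mism <- vapply(syms, function(a) sum(voting != a), integer(1))
  cand <- syms[mism <= rule$max_mismatch]
  if (length(cand) == 1L) cand else NA_character_
}

#' Which amino acid, if any, a column is conserved for
#'
#' Applies the conservation rule to the non-focal entries of one alignment
#' column. The focal species never votes; when it belongs to a focal group
#' and \code{partner_votes} is \code{FALSE}, its whole group is excluded.
#' Returns \code{NA} unless exactly one amino acid is carried by all voting
#' units except at most \code{max_mismatch} of them.
#'
#' @param record data.frame with columns \code{species} and \code{aa} (a
#'   \code{\link{column_record}}).
#' @param focal Focal species id; must be present in \code{record}.
#' @param rule A \code{\link{conservation_rule}}.
#' @return Single amino-acid character, or \code{NA_character_}.
#' @export
conserved_for <- function(record, focal, rule) {
  if (!focal %in% record$species)
    stop("focal species '", focal, "' not in column record")
  aa_col <- stats::setNames(record$aa, record$species)
  .conserved_from_states(.vote_states(aa_col, .focal_exclusion(focal, rule), rule),
                         rule)
}

.focal_exclusion <- function(focal, rule) {
  if (!rule$partner_votes) {
    for (g in rule$focal_groups) if (focal %in% g) return(g)
  }
  focal
}

#' Conservation across all species (no focal exclusion)
#'
#' @param record data.frame with columns \code{species} and \code{aa}.
#' @param rule A \code{\link{conservation_rule}}; focal groups still collapse
#'   into single voting units.
#' @return Single amino-acid character, or \code{NA_character_}.
#' @export
conserved_all <- function(record, rule) {
  aa_col <- stats::setNames(record$aa, record$species)
  .conserved_from_states(.vote_states(aa_col, character(0), rule), rule)
}

#' Codon usage of a focal species at conserved columns
#'
#' For a codon family (e.g. ATA/ATC/ATG/ATT) in one focal species, counts
#' the total occurrences of each codon over the aligned region, and how often
#' each codon sits at a column that is conserved — among the non-focal
#' species — for each context amino acid (e.g. Met and Ile). These are the
#' per-species columns of a codon-context table.
#'
#' @param ca A \code{codon_alignment}.
#' @param focal Focal species id.
#' @param family Character vector of codons to count.
#' @param contexts Character vector of context amino acids.
#' @param rule A \code{\link{conservation_rule}}.
#' @param gene Optional gene label carried into the result.
#' @return Object of class \code{codon_context_table}: list with
#'   \code{focal}, \code{gene}, \code{family}, \code{contexts}, \code{totals}
#'   (named integer per codon) and \code{context_counts} (integer matrix,
#'   codons x context amino acids).
#' @export
codon_context_table <- function(ca, focal, family, contexts, rule, gene = "") {
  stopifnot(inherits(ca, "codon_alignment"), inherits(rule, "conservation_rule"))
  if (!focal %in% ca$species)
    stop("focal species '", focal, "' not in alignment")
  family <- toupper(family); contexts <- toupper(contexts)
  totals <- stats::setNames(integer(length(family)), family)
  ctx <- matrix(0L, nrow = length(family), ncol = length(contexts),
                dimnames = list(family, contexts))
  exclude <- .focal_exclusion(focal, rule)
  for (j in seq_len(ncol(ca$cells))) {
    codon <- ca$cells[focal, j]
    if (!codon %in% family) next
    totals[codon] <- totals[codon] + 1L
    aa_col <- stats::setNames(ca$aa[, j], ca$species)
    a <- .conserved_from_states(.vote_states(aa_col, exclude, rule), rule)
    if (!is.na(a) && a %in% contexts)
      ctx[codon, a] <- ctx[codon, a] + 1L
  }
  structure(list(focal = focal, gene = gene, family = family,
                 contexts = contexts, totals = totals, context_counts = ctx,
                 rule = rule),
            class = "codon_context_table")
}

#' @export
print.codon_context_table <- function(x, ...) {
  cat("Codon context table", if (nzchar(x$gene)) paste0("(", x$gene, ")"),
      "- focal:", x$focal, "\n")
  print(as.data.frame(x))
  invisible(x)
}

#' @export
as.data.frame.codon_context_table <- function(x, ...) {
  labels <- c(paste(x$family, "number"),
              as.vector(t(outer(x$family, x$contexts, function(f, a)
                paste0(f, " on cons. ", a)))))
  counts <- c(unname(x$totals), as.vector(t(x$context_counts)))
  df <- data.frame(row = labels, count = counts, stringsAsFactors = FALSE)
  names(df)[2] <- x$focal
  df
}

#' Combine per-focal context tables into one wide table
#'
#' @param tables List of \code{codon_context_table}s sharing family and
#'   contexts (typically one per focal species, same gene).
#' @return data.frame with a \code{row} label column and one count column per
#'   focal species, in the layout of the published codon-usage tables.
#' @export
context_tables_wide <- function(tables) {
  stopifnot(length(tables) >= 1L)
  dfs <- lapply(tables, as.data.frame)
  out <- dfs[[1]]
  for (d in dfs[-1]) {
    if (!identical(d$row, out$row))
      stop("tables have differing families or contexts")
    out <- cbind(out, d[2])
  }
  out
}

#' Columns conserved for an amino acid where some species uses a focal codon
#'
#' Scans every column that is conserved for \code{target_aa} across all
#' species (no focal exclusion; groups still collapse into voting units) and
#' reports the species whose codon there belongs to \code{codon_set} — for
#' example, conserved-glycine columns where a tunicate uses an AGR codon.
#'
#' @param ca A \code{codon_alignment}.
#' @param target_aa Single amino-acid character.
#' @param codon_set Character vector of codons of interest.
#' @param rule A \code{\link{conservation_rule}}.
#' @return data.frame with columns \code{column} (1-based), \code{species},
#'   \code{codon}; zero rows when nothing qualifies.
#' @export
shared_conserved_codon_columns <- function(ca, target_aa, codon_set, rule) {
  stopifnot(inherits(ca, "codon_alignment"))
  codon_set <- toupper(codon_set)
  hits <- list()
  for (j in seq_len(ncol(ca$cells))) {
    aa_col <- stats::setNames(ca$aa[, j], ca$species)
    a <- .conserved_from_states(.vote_states(aa_col, character(0), rule), rule)
    if (is.na(a) || a != target_aa) next
    users <- ca$species[ca$cells[, j] %in% codon_set]
    if (length(users))
      hits[[length(hits) + 1L]] <- data.frame(
        column = j, species = users,
        codon = ca$cells[users, j], row.names = NULL,
        stringsAsFactors = FALSE)
  }
  if (!length(hits))
    return(data.frame(column = integer(0), species = character(0),
                      codon = character(0), stringsAsFactors = FALSE))
  do.call(rbind, hits)
}
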
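# Turning codon-context tables into candidate codon-reassignment calls, and
# annotating calls with a small-parsimony gain count on a species tree.

# residue pairs with similar physicochemistry; calls between these carry a
# caution note because substitution alone can mimic a code change
.SIMILAR_PAIRS <- c("IM", "IL", "IV", "LM", "LV", "MV",
                    "FY", "FW", "WY", "KR", "DE", "ST", "NQ", "AG")

.similar_residues <- function(a, b) {
  paste0(min(a, b), max(a, b)) %in% .SIMILAR_PAIRS
}

#' Infer candidate codon reassignments from context tables
#'
#' For every codon in the supplied tables and every context amino acid that
#' differs from the codon's assignment under \code{code}, accumulates
#' \emph{support} (occurrences of the codon at columns conserved for the
#' candidate amino acid) and \emph{conflict} (occurrences at columns
#' conserved for the current assignment) across all tables — typically one
#' table per gene, or per member of a clade when calling at clade level.
#' A call is \code{"suggested"} only when support reaches \code{min_support}
#' and conflict is zero; \code{"insufficient"} covers positive support below
#' the threshold, everything else is \code{"unsupported"}.
#'
#' @param tables List of \code{\link{codon_context_table}}s, sharing a focal
#'   species or clade.
#' @param code The \code{genetic_code} the sequences were translated with
#'   (source of the current assignment of each codon).
#' @param min_support Minimum support for a \code{"suggested"} verdict
#'   (default 2: a single instance is treated as anecdotal).
#' @param label Label for the species or clade the calls refer to; defaults
#'   to the tables' focal species joined with \code{"+"} when they differ.
#' @return data.frame of class \code{reassignment_calls} with columns
#'   \code{species_or_clade}, \code{codon}, \code{from_aa}, \code{to_aa},
#'   \code{support}, \code{conflict}, \code{verdict}, \code{note}, sorted by
#'   decreasing support.
#' @export
infer_reassignments <- function(tables, code, min_support = 2L, label = NULL) {
  if (length(tables) == 0L) stop("no context tables supplied")
  stopifnot(all(vapply(tables, inherits, logical(1), "codon_context_table")),
            inherits(code, "genetic_code"), min_support >= 1L)
  if (is.null(label)) {
    focals <- unique(vapply(tables, `[[`, character(1), "focal"))
    label <- paste(sort(focals), collapse = "+")
  }
  codons <- sort(unique(unlist(lapply(tables, `[[`, "family"))))
  contexts <- sort(unique(unlist(lapply(tables, `[[`, "contexts"))))
  count_sum <- function(codon, aa) {
    sum(vapply(tables, function(t) {
      if (codon %in% rownames(t$context_counts) &&
          aa %in% colnames(t$context_counts))
        t$context_counts[codon, aa] else 0L
    }, numeric(1)))
  }
  rows <- list()
  for (codon in codons) {
    from <- unname(code$codon_map[codon])
    for (to in setdiff(contexts, from)) {
      support <- count_sum(codon, to)
      conflict <- count_sum(codon, from)
      verdict <- if (conflict > 0) "unsupported"
        else if (support >= min_support) "suggested"
        else if (support > 0) "insufficient"
        else "unsupported"
      note <- if (from %in% .AA_SYMBOLS && to %in% .AA_SYMBOLS &&
                  .similar_residues(from, to))
        "similar residues: substitution can mimic a code change" else ""
      rows[[length(rows) + 1L]] <- data.frame(
        species_or_clade = label, codon = codon, from_aa = from, to_aa = to,
        support = support, conflict = conflict, verdict = verdict,
        note = note, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(-out$support, out$codon, out$to_aa), ]
  rownames(out) <- NULL
  class(out) <- c("reassignment_calls", class(out))
  out
}

#' Minimum number of branches on which a reassignment must arise
#'
#' Small-parsimony change count for a binary presence/absence character on a
#' rooted tree, with the root constrained to absence: the reassignment is
#' treated as derived, so a character present in every leaf still needs one
#' gain. Computed by dynamic programming over states (handles
#' multifurcations); losses count as changes too, as in Fitch parsimony.
#'
#' @param tree A rooted \code{ape} \code{phylo} object.
#' @param species Character vector of tip labels carrying the reassignment.
#' @return Integer minimum change count.
#' @export
min_reassignment_gains <- function(tree, species) {
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  missing <- setdiff(species, tree$tip.label)
  if (length(missing))
    stop("species not in tree: ", paste(missing, collapse = ", "))
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  root <- ntip + 1L
  # cost[node, s]: minimal changes in the subtree when node has state s-1
  cost <- matrix(0, nrow = nnode, ncol = 2)
  present <- tree$tip.label %in% species
  cost[seq_len(ntip), 1] <- ifelse(present, Inf, 0)
  cost[seq_len(ntip), 2] <- ifelse(present, 0, Inf)
  po <- ape::reorder.phylo(tree, "postorder")
  for (k in seq_len(nrow(po$edge))) {
    p <- po$edge[k, 1]; ch <- po$edge[k, 2]
    cost[p, 1] <- cost[p, 1] + min(cost[ch, 1], cost[ch, 2] + 1)
    cost[p, 2] <- cost[p, 2] + min(cost[ch, 1] + 1, cost[ch, 2])
  }
  as.integer(cost[root, 1])
}

#' Annotate reassignment calls with parsimony gain counts
#'
#' Splits each call's \code{species_or_clade} label on \code{"+"} and counts
#' the minimum number of independent origins of the reassignment on the tree
#' via \code{\link{min_reassignment_gains}}.
#'
#' @param calls A \code{reassignment_calls} data.frame.
#' @param tree A rooted \code{ape} \code{phylo} object.
#' @return The calls with an added integer column \code{gains}.
#' @export
parsimony_note <- function(calls, tree) {
  stopifnot(is.data.frame(calls))
  calls$gains <- vapply(calls$species_or_clade, function(lbl) {
    min_reassignment_gains(tree, strsplit(lbl, "+", fixed = TRUE)[[1]])
  }, integer(1), USE.NAMES = FALSE)
  calls
}
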
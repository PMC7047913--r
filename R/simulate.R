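# Seeded simulator of indel-free orthologous mitochondrial gene families
# along a phylogeny, with lineage-specific genetic codes and full ground
# truth, so the whole pipeline can be validated without any downloads.

#' Default 12-taxon study tree for simulations
#'
#' A fixed tunicate-like topology: three outgroup tips, three ascidian-like
#' and two thaliacean-like tips, and four appendicularian-like tips of which
#' \code{app_olongicauda}, \code{app_bstygius} and \code{app_merythro} form
#' the focal 3-taxon clade (the first two being the grouped sister pair).
#' Branch lengths (0.2--1.2 expected substitutions per variable site) model
#' deeply diverged mitochondrial proteins: variable columns are close to
#' saturation between distant tips, so that column conservation is carried
#' by the invariant fraction rather than by shallow divergence.
#'
#' @return A rooted \code{ape} \code{phylo} with 12 tips.
#' @export
sim_study_tree <- function() {
  ape::read.tree(text = paste0(
    "(((out_nematode:1.8,out_amphioxus:1.7):0.6,out_mouse:1.7):0.6,",
    "((asc_ciona:1.2,(asc_clavelina:1.1,asc_halocynthia:1.2):0.45):0.6,",
    "((thal_doliolum:1.2,thal_salpa:1.2):0.45,",
    "(app_odioica:1.5,((app_olongicauda:0.5,app_bstygius:0.5):0.45,",
    "app_merythro:0.8):0.45):0.45):0.2):0.45);"))
}

#' Tips of the focal appendicularian-like clade in the study tree
#' @return Character vector of three tip labels.
#' @export
sim_focal_clade <- function() c("app_olongicauda", "app_bstygius", "app_merythro")

#' The grouped sister pair within the focal clade
#' @return Character vector of two tip labels.
#' @export
sim_focal_pair <- function() c("app_olongicauda", "app_bstygius")

#' Simulation configuration
#'
#' @param tree Rooted \code{phylo} with branch lengths; default
#'   \code{\link{sim_study_tree}()}.
#' @param n_columns Number of codon columns (default 500).
#' @param invariant_fraction Fraction of columns held fixed at the
#'   amino-acid level (default 0.4).
#' @param substitution_rate Expected amino-acid substitutions per variable
#'   site per unit branch length (default 1).
#' @param base_code \code{genetic_code} used by every lineage not covered by
#'   \code{codes_by_clade} (default the ascidian mitochondrial code,
#'   table 13).
#' @param codes_by_clade List of \code{list(tips = <character>, code =
#'   <genetic_code>)} entries planting lineage-specific codes; tip sets must
#'   not overlap.
#' @param codon_usage Named non-negative weights per codon (unnamed codons
#'   get weight 1); synonymous codons of each amino acid are sampled
#'   proportionally to these weights.
#' @param focal_codon_boost Multiplier applied to \code{focal_codons}
#'   weights (default 3) so the codons under study are well represented.
#' @param focal_codons Codons receiving the boost (default AGA, AGG, ATA,
#'   TGA).
#' @param seed Integer RNG seed.
#' @return Object of class \code{sim_config}.
#' @export
sim_config <- function(tree = sim_study_tree(), n_columns = 500L,
                       invariant_fraction = 0.4, substitution_rate = 1,
                       base_code = get_code(13), codes_by_clade = list(),
                       codon_usage = NULL, focal_codon_boost = 3,
                       focal_codons = c("AGA", "AGG", "ATA", "TGA"),
                       seed = 1L) {
  stopifnot(inherits(tree, "phylo"), ape::is.rooted(tree),
            !is.null(tree$edge.length),
            n_columns >= 1L,
            invariant_fraction >= 0, invariant_fraction <= 1,
            substitution_rate >= 0,
            inherits(base_code, "genetic_code"))
  usage <- stats::setNames(rep(1, 64), .all_codons())
  if (!is.null(codon_usage)) {
    bad <- setdiff(names(codon_usage), names(usage))
    if (length(bad)) stop("not codons: ", paste(bad, collapse = ", "))
    if (any(codon_usage < 0)) stop("codon usage weights must be non-negative")
    usage[names(codon_usage)] <- codon_usage
  }
  usage[focal_codons] <- usage[focal_codons] * focal_codon_boost
  structure(list(tree = tree, n_columns = as.integer(n_columns),
                 invariant_fraction = invariant_fraction,
                 substitution_rate = substitution_rate,
                 base_code = base_code, codes_by_clade = codes_by_clade,
                 codon_usage = usage, seed = as.integer(seed)),
            class = "sim_config")
}

#' Configuration with one planted ATA Met-to-Ile reassignment
#'
#' Study conditions used throughout validation: the default tree, 500 codon
#' columns, 40\% invariant columns, and the focal 3-taxon clade carrying the
#' ascidian code with ATA reassigned from Met back to Ile (as in the
#' echinoderm code).
#'
#' @param seed Integer RNG seed.
#' @param planted Logical; \code{FALSE} gives the matched null configuration
#'   in which every lineage keeps the base code.
#' @return A \code{sim_config}.
#' @export
sim_planted_ata_config <- function(seed = 1L, planted = TRUE) {
  clades <- if (planted) {
    list(list(tips = sim_focal_clade(),
              code = derive_code(get_code(13), c(ATA = "I"))))
  } else list()
  sim_config(codes_by_clade = clades, seed = seed)
}

.assign_tip_codes <- function(config) {
  tips <- config$tree$tip.label
  codes <- stats::setNames(rep(list(config$base_code), length(tips)), tips)
  seen <- character(0)
  for (entry in config$codes_by_clade) {
    bad <- setdiff(entry$tips, tips)
    if (length(bad))
      stop("codes_by_clade names unknown tips: ", paste(bad, collapse = ", "))
    overlap <- intersect(entry$tips, seen)
    if (length(overlap))
      stop("overlapping clade code assignments for: ",
           paste(overlap, collapse = ", "))
    seen <- c(seen, entry$tips)
    for (tp in entry$tips) codes[[tp]] <- entry$code
  }
  codes
}

# evolve one amino acid through k uniform replacement events
.mutate_chain <- function(aa, k) {
  for (i in seq_len(k)) aa <- sample(setdiff(.AA_SYMBOLS, aa), 1L)
  aa
}

#' Simulate an indel-free orthologous gene family with ground truth
#'
#' Amino acids evolve from a uniform-random root sequence by a Poisson
#' process of uniform replacements on the non-invariant columns
#' (rate \eqn{=} \code{substitution_rate} \eqn{\times} branch length); each
#' tip's codons are then drawn per column from the synonymous codons of its
#' own (possibly planted) genetic code, proportionally to the configured
#' codon-usage weights. The same configuration, including the seed, always
#' yields the identical dataset.
#'
#' @param config A \code{\link{sim_config}}.
#' @return Object of class \code{synthetic_dataset}: list with
#'   \code{protein_alignment} (true amino-acid rows, indel-free),
#'   \code{cds_by_species}, \code{true_codes}, \code{truth_calls} (expected
#'   reassignment triples derived from the planted codes), \code{tree},
#'   \code{invariant_columns} and \code{config}.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  true_codes <- .assign_tip_codes(config)  # validates before touching RNG
  set.seed(config$seed)
  tree <- config$tree
  ntip <- length(tree$tip.label)
  n <- config$n_columns
  root_seq <- sample(.AA_SYMBOLS, n, replace = TRUE)
  n_inv <- round(config$invariant_fraction * n)
  invariant <- sort(sample.int(n, n_inv))
  variable <- setdiff(seq_len(n), invariant)

  seqs <- vector("list", ntip + tree$Nnode)
  seqs[[ntip + 1L]] <- root_seq
  cw <- ape::reorder.phylo(tree, "cladewise")  # parents before children
  for (k in seq_len(nrow(cw$edge))) {
    p <- cw$edge[k, 1]; ch <- cw$edge[k, 2]
    s <- seqs[[p]]
    if (length(variable)) {
      nsub <- stats::rpois(length(variable),
                           config$substitution_rate * cw$edge.length[k])
      hit <- which(nsub > 0L)
      for (i in hit)
        s[variable[i]] <- .mutate_chain(s[variable[i]], nsub[i])
    }
    seqs[[ch]] <- s
  }

  usage <- config$codon_usage
  cds <- stats::setNames(vector("list", ntip), tree$tip.label)
  prot <- stats::setNames(character(ntip), tree$tip.label)
  for (t in seq_len(ntip)) {
    tip <- tree$tip.label[t]
    aa_seq <- seqs[[t]]
    map <- true_codes[[tip]]$codon_map
    codons <- character(n)
    for (a in unique(aa_seq)) {
      syn <- names(map)[map == a]
      w <- usage[syn]
      if (!any(w > 0))
        stop("no positive-weight codon for amino acid '", a,
             "' under code of tip '", tip, "'")
      at <- which(aa_seq == a)
      codons[at] <- if (length(syn) == 1L) syn else
        sample(syn, length(at), replace = TRUE, prob = w)
    }
    cds[[tip]] <- paste(codons, collapse = "")
    prot[tip] <- paste(aa_seq, collapse = "")
  }

  truth <- list()
  for (entry in config$codes_by_clade) {
    d <- code_diff(config$base_code, entry$code)
    for (i in seq_len(nrow(d)))
      truth[[length(truth) + 1L]] <- data.frame(
        species_or_clade = paste(sort(entry$tips), collapse = "+"),
        codon = d$codon[i], from_aa = d$aa_a[i], to_aa = d$aa_b[i],
        stringsAsFactors = FALSE)
  }
  truth_calls <- if (length(truth)) do.call(rbind, truth) else
    data.frame(species_or_clade = character(0), codon = character(0),
               from_aa = character(0), to_aa = character(0),
               stringsAsFactors = FALSE)

  structure(list(protein_alignment = protein_alignment(prot),
                 cds_by_species = unlist(cds),
                 true_codes = true_codes,
                 truth_calls = truth_calls,
                 tree = tree,
                 invariant_columns = invariant,
                 config = config),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("Synthetic dataset:", length(x$cds_by_species), "species x",
      x$config$n_columns, "codon columns;",
      nrow(x$truth_calls), "planted reassignment(s)\n")
  invisible(x)
}

#' Precision and recall of suggested calls against planted truth
#'
#' Exact set comparison of (species/clade label, codon, target amino acid)
#' triples between the \code{"suggested"} calls and the dataset's
#' \code{truth_calls}. With no suggested calls precision is vacuously 1;
#' with empty truth recall is 1.
#'
#' @param dataset A \code{synthetic_dataset}.
#' @param calls A \code{reassignment_calls} data.frame.
#' @return List with \code{precision}, \code{recall}, \code{tp}, \code{fp},
#'   \code{fn}.
#' @export
recovery_report <- function(dataset, calls) {
  stopifnot(inherits(dataset, "synthetic_dataset"), is.data.frame(calls))
  sug <- calls[calls$verdict == "suggested", , drop = FALSE]
  key <- function(df) if (nrow(df) == 0L) character(0) else
    paste(df$species_or_clade, df$codon, df$to_aa, sep = "|")
  got <- unique(key(sug)); want <- unique(key(dataset$truth_calls))
  tp <- length(intersect(got, want))
  fp <- length(setdiff(got, want))
  fn <- length(setdiff(want, got))
  list(precision = if (length(got)) tp / length(got) else 1,
       recall = if (length(want)) tp / length(want) else 1,
       tp = tp, fp = fp, fn = fn)
}
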
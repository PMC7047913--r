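# End-to-end drivers: build a codon alignment straight from coding
# sequences, call reassignments at clade level, and a config-driven
# pipeline that writes the report bundle (tables TSV, calls JSON, run log).

#' Build a codon alignment directly from in-frame coding sequences
#'
#' Translates every coding sequence under its assumed code and, when the
#' translations all have equal length, uses the identity alignment (no
#' external aligner): this is the indel-free case, e.g. simulator output or
#' pre-trimmed orthologues. Unequal lengths require a protein MSA computed
#' elsewhere and threaded with \code{\link{thread_codons}}.
#'
#' @param cds_by_species Named character vector of coding sequences.
#' @param codes A single \code{genetic_code} or named list per species.
#' @return A \code{codon_alignment}.
#' @export
codon_alignment_from_cds <- function(cds_by_species, codes) {
  species <- names(cds_by_species)
  stopifnot(!is.null(species), length(species) >= 2L)
  if (inherits(codes, "genetic_code"))
    codes <- stats::setNames(rep(list(codes), length(species)), species)
  prot <- vapply(species, function(sp)
    translate_cds(cds_by_species[[sp]], codes[[sp]]), character(1))
  if (length(unique(nchar(prot))) != 1L)
    stop("translated lengths differ (",
         paste(unique(nchar(prot)), collapse = ", "),
         "); supply a protein alignment and use thread_codons()")
  thread_codons(protein_alignment(prot), cds_by_species, codes)
}

#' Clade-level reassignment calls
#'
#' Builds one codon-context table per clade member and codon family, sums
#' them, and infers reassignment calls labelled with the clade (member ids
#' sorted and joined with \code{"+"}). This mirrors pooling the evidence of
#' closely related species across one or more genes.
#'
#' @param ca A \code{codon_alignment} (or a list of them, one per gene; the
#'   tables of all genes are pooled).
#' @param clade Character vector of member species ids.
#' @param code Assumed \code{genetic_code} (current assignments).
#' @param rule A \code{\link{conservation_rule}}.
#' @param families Named list of codon vectors, e.g.
#'   \code{list(ATN = c("ATA","ATC","ATG","ATT"))}.
#' @param contexts Named list, parallel to \code{families}, of context amino
#'   acids, e.g. \code{list(ATN = c("M","I"))}.
#' @param min_support Minimum support for a suggested verdict.
#' @return A \code{reassignment_calls} data.frame.
#' @export
clade_calls <- function(ca, clade, code, rule, families, contexts,
                        min_support = 2L) {
  alns <- if (inherits(ca, "codon_alignment")) list(ca) else ca
  stopifnot(identical(names(families), names(contexts)))
  tables <- list()
  for (aln in alns)
    for (fam in names(families))
      for (sp in clade)
        tables[[length(tables) + 1L]] <- codon_context_table(
          aln, sp, families[[fam]], contexts[[fam]], rule, gene = fam)
  infer_reassignments(tables, code, min_support,
                      label = paste(sort(clade), collapse = "+"))
}

.default_families <- function() {
  list(ATN = c("ATA", "ATC", "ATG", "ATT"), TGR = c("TGA", "TGG"))
}

.default_contexts <- function() list(ATN = c("M", "I"), TGR = c("W", "R"))

#' Run the whole assessment pipeline from a configuration
#'
#' Reads coding sequences (and optionally a protein MSA), threads codons,
#' computes per-focal codon-context tables for each codon family, infers
#' per-species and optional clade-level reassignment calls, and writes the
#' report bundle: one wide TSV per family, \code{calls.tsv},
#' \code{calls.json} and \code{run_log.txt} (parameters plus input
#' checksums). Outputs are staged and only moved into \code{out_dir} on
#' success, so a failed run leaves no partial bundle.
#'
#' @param config Either a path to a YAML file or a named list with fields:
#'   \code{cds_fasta} (required), \code{out_dir} (required),
#'   \code{protein_msa} (optional path), \code{msa_format}
#'   (\code{"fasta"}/\code{"clustal"}), \code{code_table} (single NCBI table
#'   number, default 13) or \code{codes_by_species} (named table numbers),
#'   \code{focal} (species to tabulate; default all), \code{focal_groups}
#'   (list of grouped species), \code{max_mismatch} (default 1),
#'   \code{count_gaps_as_mismatch}, \code{families}/\code{contexts} (named
#'   lists; defaults ATN with Met/Ile and TGR with Trp/Arg),
#'   \code{min_support} (default 2), \code{clades} (list of species vectors
#'   for clade-level calls), \code{tree} (newick path for parsimony notes).
#' @return Invisibly, a list with \code{tables} (per family, wide
#'   data.frame), \code{calls} and the output paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stage <- "configuration"
  fail <- function(e) stop("pipeline failed at stage '", stage, "': ",
                           conditionMessage(e), call. = FALSE)
  tryCatch({
    for (req in c("cds_fasta", "out_dir"))
      if (is.null(config[[req]])) stop("missing required field '", req, "'")

    stage <- "read inputs"
    cds <- read_fasta(config[["cds_fasta"]])
    if (length(cds) == 0L) stop("no sequences in ", config[["cds_fasta"]])
    checksums <- tools::md5sum(config[["cds_fasta"]])
    species <- names(cds)
    codes <- if (!is.null(config[["codes_by_species"]])) {
      lapply(config[["codes_by_species"]], get_code)
    } else {
      tab <- if (is.null(config[["code_table"]])) 13L else config[["code_table"]]
      stats::setNames(rep(list(get_code(tab)), length(species)), species)
    }

    stage <- "codon alignment"
    ca <- if (!is.null(config[["protein_msa"]])) {
      checksums <- c(checksums, tools::md5sum(config[["protein_msa"]]))
      fmt <- if (is.null(config[["msa_format"]])) "fasta" else config[["msa_format"]]
      thread_codons(read_protein_alignment(config[["protein_msa"]], fmt), cds, codes)
    } else {
      codon_alignment_from_cds(cds, codes)
    }

    stage <- "conservation tables"
    rule <- conservation_rule(
      max_mismatch = if (is.null(config[["max_mismatch"]])) 1L else config[["max_mismatch"]],
      focal_groups = if (is.null(config[["focal_groups"]])) list() else config[["focal_groups"]],
      count_gaps_as_mismatch = isTRUE(config[["count_gaps_as_mismatch"]]))
    families <- if (is.null(config[["families"]])) .default_families() else
      lapply(config[["families"]], toupper)
    contexts <- if (is.null(config[["contexts"]])) .default_contexts() else
      lapply(config[["contexts"]], toupper)
    focal <- if (is.null(config[["focal"]])) ca$species else config[["focal"]]
    tables <- lapply(names(families), function(fam) {
      per_focal <- lapply(focal, function(sp)
        codon_context_table(ca, sp, families[[fam]], contexts[[fam]],
                            rule, gene = fam))
      list(name = fam, wide = context_tables_wide(per_focal),
           tables = per_focal)
    })
    names(tables) <- names(families)

    stage <- "reassignment inference"
    min_support <- if (is.null(config[["min_support"]])) 2L else config[["min_support"]]
    assumed <- codes[[1]]
    calls <- do.call(rbind, lapply(focal, function(sp) {
      infer_reassignments(
        unlist(lapply(tables, function(t)
          t$tables[match(sp, focal)]), recursive = FALSE),
        assumed, min_support, label = sp)
    }))
    for (cl in config[["clades"]])
      calls <- rbind(calls, clade_calls(ca, cl, assumed, rule, families,
                                        contexts, min_support))
    if (!is.null(config[["tree"]])) {
      checksums <- c(checksums, tools::md5sum(config[["tree"]]))
      calls <- parsimony_note(calls, ape::read.tree(config[["tree"]]))
    }

    stage <- "write outputs"
    staging <- tempfile("mitocode_out_")
    dir.create(staging)
    on.exit(unlink(staging, recursive = TRUE), add = TRUE)
    for (fam in names(tables))
      utils::write.table(tables[[fam]]$wide,
                         file.path(staging, paste0("table_", fam, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(calls, file.path(staging, "calls.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(calls, file.path(staging, "calls.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
    log_lines <- c(
      paste0("mitocode run ", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
      paste0("parameter max_mismatch=", rule$max_mismatch),
      paste0("parameter count_gaps_as_mismatch=", rule$count_gaps_as_mismatch),
      paste0("parameter min_support=", min_support),
      paste0("parameter families=",
             paste(vapply(names(families), function(f)
               paste0(f, ":", paste(families[[f]], collapse = ",")),
               character(1)), collapse = "; ")),
      paste0("parameter focal=", paste(focal, collapse = ",")),
      paste0("input md5 ", names(checksums), "=", unname(checksums)))
    writeLines(log_lines, file.path(staging, "run_log.txt"))

    if (!dir.exists(config[["out_dir"]]))
      dir.create(config[["out_dir"]], recursive = TRUE)
    produced <- list.files(staging, full.names = TRUE)
    ok <- file.copy(produced, config[["out_dir"]], overwrite = TRUE)
    if (!all(ok)) stop("could not move outputs into ", config[["out_dir"]])

    invisible(list(tables = lapply(tables, `[[`, "wide"), calls = calls,
                   out_dir = config[["out_dir"]],
                   files = file.path(config[["out_dir"]], basename(produced))))
  }, error = fail)
}
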
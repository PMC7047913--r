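# Region extraction with GenBank-style bracket coordinates and consensus
# building from pre-aligned EST-like fragment sets.

.IUPAC_DNA <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                "B", "D", "H", "V", "N")

.check_iupac <- function(seq, allow_gap = FALSE) {
  chars <- strsplit(toupper(seq), "")[[1]]
  ok <- .IUPAC_DNA
  if (allow_gap) ok <- c(ok, "-")
  bad <- which(!chars %in% ok)
  if (length(bad))
    stop("invalid DNA symbol '", chars[bad[1]], "' at position ", bad[1])
  invisible(chars)
}

#' Reverse complement of an IUPAC DNA string
#'
#' @param seq A single DNA string; IUPAC ambiguity codes allowed.
#' @return The reverse complement, uppercase.
#' @export
reverse_complement <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (nchar(seq) == 0L) return("")
  .check_iupac(seq)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(toupper(seq))))
}

#' Parse a GenBank-bracket region specification
#'
#' Parses strings such as \code{"SCLE01415711.1[8054:6522]"}: accession plus
#' 1-based inclusive start and end. Start greater than end encodes the
#' reverse strand.
#'
#' @param text A single region string \code{"ACC[START:END]"}.
#' @return A \code{region_spec}: list with \code{accession}, \code{start},
#'   \code{end}, \code{reverse} (logical).
#' @export
parse_region <- function(text) {
  m <- regmatches(text, regexec("^(.+)\\[([0-9]+):([0-9]+)\\]$", text))[[1]]
  if (length(m) != 4L)
    stop("cannot parse region '", text, "'; expected ACCESSION[START:END]")
  region_spec(m[2], as.integer(m[3]), as.integer(m[4]))
}

#' @rdname parse_region
#' @param accession Accession or contig id.
#' @param start,end 1-based inclusive coordinates (both >= 1).
#' @export
region_spec <- function(accession, start, end) {
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 1L || end < 1L)
    stop("region coordinates must be >= 1")
  structure(list(accession = accession, start = start, end = end,
                 reverse = start > end),
            class = "region_spec")
}

#' Extract a gene region from a contig
#'
#' Coordinates are 1-based inclusive. If \code{start > end} the region is
#' taken on the reverse strand: the forward slice \code{[end, start]} is
#' reverse-complemented. With \code{circular = TRUE} coordinates may run past
#' the contig end and wrap the origin (position \code{len + k} reads position
#' \code{k}).
#'
#' @param contig A single DNA string.
#' @param region A \code{region_spec} (or a bracket string parsed with
#'   \code{\link{parse_region}}).
#' @param circular Logical; allow coordinates to wrap the origin.
#' @return The extracted sequence with attribute \code{source} recording
#'   accession, coordinates and strand.
#' @export
extract_region <- function(contig, region, circular = FALSE) {
  if (is.character(region)) region <- parse_region(region)
  stopifnot(inherits(region, "region_spec"))
  len <- nchar(contig)
  hi <- max(region$start, region$end)
  if (hi > len && !circular)
    stop("region [", region$start, ":", region$end, "] exceeds contig '",
         region$accession, "' length ", len)
  lo <- min(region$start, region$end)
  idx <- lo:hi
  if (circular) idx <- ((idx - 1L) %% len) + 1L
  chars <- strsplit(toupper(contig), "")[[1]]
  out <- paste(chars[idx], collapse = "")
  if (region$reverse) out <- reverse_complement(out)
  attr(out, "source") <- list(accession = region$accession,
                              start = region$start, end = region$end,
                              strand = if (region$reverse) "-" else "+",
                              circular = circular)
  out
}

#' Read / write FASTA files
#'
#' Thin wrappers around Biostrings returning plain named character vectors,
#' which is the currency of this package. \code{read_fasta} accepts any
#' alphabet (nucleotide, protein, gapped alignments).
#'
#' @param path File path.
#' @return \code{read_fasta}: named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  out <- toupper(as.character(x))
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' @rdname read_fasta
#' @param seqs Named character vector of sequences.
#' @param width Line-wrap width.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  stopifnot(!is.null(names(seqs)), all(nzchar(names(seqs))))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    n <- nchar(s)
    if (n == 0L) next
    starts <- seq(1L, n, by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, n)), con)
  }
  invisible(path)
}

.fragment_matrix <- function(frags) {
  if (length(frags) == 0L) stop("fragment set is empty")
  lens <- nchar(frags)
  if (length(unique(lens)) != 1L)
    stop("fragments must be pre-aligned to equal length; got lengths ",
         paste(unique(lens), collapse = ", "))
  ids <- names(frags)
  if (is.null(ids)) ids <- paste0("frag", seq_along(frags))
  m <- do.call(rbind, strsplit(toupper(frags), ""))
  rownames(m) <- ids
  m
}

.CONSENSUS_ORDER <- c("A", "C", "G", "T", "N",
                      setdiff(.IUPAC_DNA, c("A", "C", "G", "T", "N")))

#' Majority consensus of an aligned fragment set
#'
#' Per column the most frequent non-gap symbol wins; columns that are gaps in
#' every fragment are dropped. Ties are broken by the fixed symbol order
#' A < C < G < T < N (then remaining IUPAC codes alphabetically) and flagged
#' in the support table so they can be audited.
#'
#' @param frags Named character vector of equal-length gapped sequences.
#' @return List of class \code{consensus_result} with \code{sequence} (the
#'   ungapped consensus) and \code{support}, a data.frame per consensus
#'   position: \code{position}, \code{symbol}, \code{agreeing} (fragments
#'   carrying the chosen symbol), \code{coverage} (non-gap fragments) and
#'   \code{tie}.
#' @export
majority_consensus <- function(frags) {
  m <- .fragment_matrix(frags)
  keep <- which(colSums(m != "-") > 0L)
  sym <- character(length(keep)); agree <- integer(length(keep))
  cov <- integer(length(keep)); tie <- logical(length(keep))
  for (k in seq_along(keep)) {
    col <- m[, keep[k]]
    col <- col[col != "-"]
    tab <- table(col)
    best <- names(tab)[tab == max(tab)]
    pick <- best[order(match(best, .CONSENSUS_ORDER, nomatch = length(.CONSENSUS_ORDER) + 1L), best)][1]
    sym[k] <- pick
    agree[k] <- tab[[pick]]
    cov[k] <- length(col)
    tie[k] <- length(best) > 1L
  }
  structure(
    list(sequence = paste(sym, collapse = ""),
         support = data.frame(position = seq_along(keep), symbol = sym,
                              agreeing = agree, coverage = cov, tie = tie,
                              stringsAsFactors = FALSE)),
    class = "consensus_result")
}

#' Group aligned fragments into haplotypes
#'
#' Variable columns are those with at least two distinct non-gap symbols.
#' Two fragments are compatible when they agree at every variable column
#' where both are non-gap; haplotype groups are the transitive closure
#' (single linkage) of this relation, so fragments that never overlap at a
#' variable column join through intermediates. Singletons are allowed.
#'
#' @param frags Named character vector of equal-length gapped sequences.
#' @return List of character vectors of fragment ids, one per haplotype
#'   group, ordered by first appearance.
#' @export
group_haplotypes <- function(frags) {
  m <- .fragment_matrix(frags)
  n <- nrow(m)
  var_cols <- which(apply(m, 2, function(col) {
    length(unique(col[col != "-"])) >= 2L
  }))
  comp <- matrix(TRUE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) if (i < j) {
    both <- var_cols[m[i, var_cols] != "-" & m[j, var_cols] != "-"]
    ok <- all(m[i, both] == m[j, both])
    comp[i, j] <- comp[j, i] <- ok
  }
  # connected components of the compatibility graph
  group <- rep(NA_integer_, n)
  g <- 0L
  for (s in seq_len(n)) {
    if (!is.na(group[s])) next
    g <- g + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(group[v])) next
      group[v] <- g
      queue <- c(queue, which(comp[v, ] & is.na(group)))
    }
  }
  lapply(seq_len(g), function(k) rownames(m)[group == k])
}
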
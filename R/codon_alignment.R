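# Threading coding sequences onto a protein MSA ("back-translation") and the
# per-column transposed view used to interrogate codon usage.

#' Construct a protein alignment object
#'
#' @param rows Named character vector of equal-length aligned amino-acid
#'   strings (symbols: amino acids, \code{"*"}, \code{"X"}, \code{"-"}).
#' @return Object of class \code{protein_alignment}: list with \code{rows}
#'   and \code{width}.
#' @export
protein_alignment <- function(rows) {
  stopifnot(is.character(rows), length(rows) >= 2L, !is.null(names(rows)))
  rows <- toupper(rows)
  w <- unique(nchar(rows))
  if (length(w) != 1L)
    stop("alignment rows differ in length: ", paste(w, collapse = ", "))
  structure(list(rows = rows, width = w), class = "protein_alignment")
}

#' Read a protein multiple alignment from aligned FASTA or Clustal
#'
#' @param path File path.
#' @param format \code{"fasta"} or \code{"clustal"}.
#' @return A \code{protein_alignment}.
#' @export
read_protein_alignment <- function(path, format = c("fasta", "clustal")) {
  format <- match.arg(format)
  rows <- if (format == "fasta") {
    read_fasta(path)
  } else {
    toupper(as.character(Biostrings::readAAMultipleAlignment(path,
                                                             format = "clustal")))
  }
  protein_alignment(rows)
}

#' Thread coding sequences onto a protein alignment
#'
#' Places each species' codons under the corresponding residues of the
#' protein MSA, inserting the gap cell \code{"---"} wherever the protein row
#' has \code{"-"}. Each codon must translate, under that species' code, to
#' the protein character above it (a protein \code{"X"} accepts any codon).
#'
#' @param pa A \code{protein_alignment}.
#' @param cds_by_species Named character vector or list of unaligned coding
#'   sequences, one per alignment row.
#' @param codes Either a single \code{genetic_code} used for every species or
#'   a named list of codes per species.
#' @return Object of class \code{codon_alignment}: list with \code{species},
#'   \code{aa} and \code{cells} (character matrices, species x columns) and
#'   \code{codes} (named list).
#' @examples
#' pa <- protein_alignment(c(a = "M-G", b = "MAG"))
#' ca <- thread_codons(pa, c(a = "ATGGGA", b = "ATGGCTGGT"), get_code(13))
#' ca$cells["a", ]  # "ATG" "---" "GGA"
#' @export
thread_codons <- function(pa, cds_by_species, codes) {
  stopifnot(inherits(pa, "protein_alignment"))
  species <- names(pa$rows)
  if (inherits(codes, "genetic_code"))
    codes <- stats::setNames(rep(list(codes), length(species)), species)
  missing_cds <- setdiff(species, names(cds_by_species))
  if (length(missing_cds))
    stop("no coding sequence for species: ", paste(missing_cds, collapse = ", "))
  missing_code <- setdiff(species, names(codes))
  if (length(missing_code))
    stop("no genetic code for species: ", paste(missing_code, collapse = ", "))
  aa <- do.call(rbind, strsplit(pa$rows, ""))
  rownames(aa) <- species
  cells <- matrix("---", nrow = length(species), ncol = pa$width,
                  dimnames = list(species, NULL))
  for (sp in species) {
    cds <- toupper(as.character(cds_by_species[[sp]]))
    resi <- which(aa[sp, ] != "-")
    n_expect <- length(resi)
    if (nchar(cds) %% 3L != 0L)
      stop("species '", sp, "': coding sequence length ", nchar(cds),
           " is not a multiple of 3")
    n_actual <- nchar(cds) %/% 3L
    if (n_actual != n_expect)
      stop("species '", sp, "': protein row has ", n_expect,
           " residues but coding sequence has ", n_actual, " codons")
    codons <- .split_codons(cds)
    tr <- unname(codes[[sp]]$codon_map[codons])
    tr[is.na(tr)] <- "X"
    expect <- aa[sp, resi]
    bad <- which(expect != "X" & tr != expect)
    if (length(bad))
      stop("species '", sp, "': codon ", codons[bad[1]], " translates to '",
           tr[bad[1]], "' but the protein alignment has '", expect[bad[1]],
           "' at column ", resi[bad[1]])
    cells[sp, resi] <- codons
  }
  structure(list(species = species, aa = aa, cells = cells,
                 codes = codes[species]),
            class = "codon_alignment")
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat("Codon alignment:", length(x$species), "species x",
      ncol(x$cells), "columns\n")
  invisible(x)
}

#' Extract one alignment column as a record
#'
#' @param ca A \code{codon_alignment}.
#' @param column 1-based column index.
#' @return data.frame with one row per species: \code{species}, \code{aa},
#'   \code{codon} (\code{"---"} for gap).
#' @export
column_record <- function(ca, column) {
  stopifnot(inherits(ca, "codon_alignment"),
            column >= 1L, column <= ncol(ca$cells))
  data.frame(species = ca$species, aa = ca$aa[, column],
             codon = ca$cells[, column], row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Transpose a codon alignment into per-column records
#'
#' One output row per (column, species) pair, columns in order, mirroring a
#' file in which each line is a single alignment position.
#'
#' @param ca A \code{codon_alignment}.
#' @return data.frame with columns \code{column} (1-based), \code{species},
#'   \code{aa}, \code{codon}.
#' @export
transpose_columns <- function(ca) {
  stopifnot(inherits(ca, "codon_alignment"))
  w <- ncol(ca$cells); n <- length(ca$species)
  data.frame(
    column = rep(seq_len(w), each = n),
    species = rep(ca$species, times = w),
    aa = as.vector(ca$aa),
    codon = as.vector(ca$cells),
    stringsAsFactors = FALSE)
}

#' Rebuild a codon alignment from its transposed form
#'
#' Inverse of \code{\link{transpose_columns}} (codes are not carried through
#' the tabular form and are left empty unless supplied).
#'
#' @param df data.frame as produced by \code{transpose_columns}.
#' @param codes Optional named list of \code{genetic_code}s per species.
#' @return A \code{codon_alignment}.
#' @export
rebuild_alignment <- function(df, codes = NULL) {
  species <- unique(df$species)
  w <- max(df$column)
  o <- order(df$column, match(df$species, species))
  df <- df[o, ]
  aa <- matrix(df$aa, nrow = length(species), ncol = w,
               dimnames = list(species, NULL))
  cells <- matrix(df$codon, nrow = length(species), ncol = w,
                  dimnames = list(species, NULL))
  structure(list(species = species, aa = aa, cells = cells, codes = codes),
            class = "codon_alignment")
}

#' Per-row differences to the alignment consensus
#'
#' The consensus symbol of a column is its most frequent non-gap symbol
#' (ties broken alphabetically). For each row, reports the 1-based columns
#' where the row differs from the consensus; a gap in the row counts as a
#' difference only where the consensus is non-gap.
#'
#' @param pa A \code{protein_alignment}.
#' @return Named list (one entry per row) of integer column vectors.
#' @export
differences_to_consensus <- function(pa) {
  stopifnot(inherits(pa, "protein_alignment"))
  m <- do.call(rbind, strsplit(pa$rows, ""))
  rownames(m) <- names(pa$rows)
  cons <- apply(m, 2, function(col) {
    col <- col[col != "-"]
    if (!length(col)) return("-")
    tab <- table(col)
    sort(names(tab)[tab == max(tab)])[1]
  })
  out <- lapply(rownames(m), function(sp) {
    row <- m[sp, ]
    which(cons != "-" & row != cons)
  })
  stats::setNames(out, rownames(m))
}

#' Write / read the interleaved three-lines-per-species codon alignment text
#'
#' The dialect written is, per species: a header line \code{">id"}, the
#' aligned amino-acid row, the aligned codon row (cells joined by single
#' spaces, gaps as \code{"---"}), then a blank spacer line.
#'
#' @param ca A \code{codon_alignment}.
#' @param path File path.
#' @return Invisibly, the path (\code{write_codon_alignment}) or a
#'   \code{codon_alignment} (\code{read_codon_alignment}).
#' @export
write_codon_alignment <- function(ca, path) {
  stopifnot(inherits(ca, "codon_alignment"))
  con <- file(path, "w")
  on.exit(close(con))
  for (sp in ca$species) {
    writeLines(c(paste0(">", sp),
                 paste(ca$aa[sp, ], collapse = ""),
                 paste(ca$cells[sp, ], collapse = " "),
                 ""), con)
  }
  invisible(path)
}

#' @rdname write_codon_alignment
#' @export
read_codon_alignment <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) %% 3L != 0L)
    stop("malformed codon-alignment file: expected blocks of 3 lines")
  n <- length(lines) %/% 3L
  species <- character(n)
  aa_rows <- vector("list", n); cell_rows <- vector("list", n)
  for (i in seq_len(n)) {
    hdr <- lines[3L * i - 2L]
    if (!startsWith(hdr, ">"))
      stop("malformed codon-alignment file: expected '>' header, got '", hdr, "'")
    species[i] <- sub("^>", "", hdr)
    aa_rows[[i]] <- strsplit(lines[3L * i - 1L], "")[[1]]
    cell_rows[[i]] <- strsplit(trimws(lines[3L * i]), "[[:space:]]+")[[1]]
    if (length(aa_rows[[i]]) != length(cell_rows[[i]]))
      stop("species '", species[i], "': amino-acid row has ",
           length(aa_rows[[i]]), " columns but codon row has ",
           length(cell_rows[[i]]))
  }
  aa <- do.call(rbind, aa_rows); cells <- do.call(rbind, cell_rows)
  rownames(aa) <- rownames(cells) <- species
  structure(list(species = species, aa = aa, cells = cells, codes = NULL),
            class = "codon_alignment")
}

#' Write the per-column TSV view of a codon alignment
#'
#' @param ca A \code{codon_alignment}.
#' @param path File path.
#' @return Invisibly, the path.
#' @export
write_column_tsv <- function(ca, path) {
  utils::write.table(transpose_columns(ca), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
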
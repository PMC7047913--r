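# Frozen NCBI-style translation tables. Codon order is the conventional
# T,C,A,G nesting (TTT, TTC, TTA, TTG, TCT, ...); tables are stored as the
# standard code plus per-table reassignments so each alternative code is
# readable as a diff from table 1.

.CODON_BASES <- c("T", "C", "A", "G")

.all_codons <- function() {
  as.vector(vapply(.CODON_BASES, function(b1)
    vapply(.CODON_BASES, function(b2)
      paste0(b1, b2, .CODON_BASES), character(4)), character(16)))
}

.STANDARD_AA <- "FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRRIIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG"

.CODE_DEFS <- list(
  `1` = list(
    name = "standard",
    reassign = character(0),
    starts = c("TTG", "CTG", "ATG")),
  `2` = list(
    name = "vertebrate mitochondrial",
    reassign = c(AGA = "*", AGG = "*", ATA = "M", TGA = "W"),
    starts = c("ATT", "ATC", "ATA", "ATG", "GTG")),
  `5` = list(
    name = "invertebrate mitochondrial",
    reassign = c(AGA = "S", AGG = "S", ATA = "M", TGA = "W"),
    starts = c("TTG", "ATT", "ATC", "ATA", "ATG", "GTG")),
  `9` = list(
    name = "echinoderm/flatworm mitochondrial",
    reassign = c(AAA = "N", AGA = "S", AGG = "S", TGA = "W"),
    starts = c("ATG", "GTG")),
  `13` = list(
    name = "ascidian mitochondrial",
    reassign = c(AGA = "G", AGG = "G", ATA = "M", TGA = "W"),
    starts = c("TTG", "ATA", "ATG", "GTG"))
)

.AA_SYMBOLS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
                 "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Retrieve a mitochondrial (or standard) genetic code
#'
#' Returns one of the translation tables frozen in the package: 1 (standard),
#' 2 (vertebrate mitochondrial), 5 (invertebrate mitochondrial),
#' 9 (echinoderm/flatworm mitochondrial) or 13 (ascidian mitochondrial).
#' Table numbers follow the NCBI convention. The ascidian code differs from
#' the invertebrate one by AGA/AGG encoding glycine rather than serine, and
#' from the vertebrate one where AGR are stop codons; ATA encodes Met and TGA
#' Trp in all three mitochondrial codes, whereas table 9 keeps ATA as Ile.
#'
#' @param table_id Integer translation-table number; one of 1, 2, 5, 9, 13.
#' @return An object of class \code{genetic_code}: a list with
#'   \code{table_id}, \code{name}, \code{codon_map} (named character vector of
#'   all 64 codons to one-letter amino acids or \code{"*"}) and
#'   \code{start_codons} (informational).
#' @examples
#' asc <- get_code(13)
#' asc$codon_map[c("AGA", "AGG", "ATA", "TGA")]
#' @export
get_code <- function(table_id) {
  key <- as.character(table_id)
  if (length(key) != 1L || !key %in% names(.CODE_DEFS)) {
    stop("unknown code table '", table_id, "'; supported tables: ",
         paste(names(.CODE_DEFS), collapse = ", "))
  }
  def <- .CODE_DEFS[[key]]
  codons <- .all_codons()
  map <- strsplit(.STANDARD_AA, "")[[1]]
  names(map) <- codons
  map[names(def$reassign)] <- def$reassign
  structure(
    list(table_id = as.integer(table_id), name = def$name,
         codon_map = map, start_codons = def$starts),
    class = "genetic_code")
}

#' Derive a custom code from an existing one
#'
#' Used mainly by the simulator to plant lineage-specific reassignments
#' (for example ATA from Met back to Ile on top of the ascidian code).
#'
#' @param base A \code{genetic_code}.
#' @param reassignments Named character vector, names are codons and values
#'   the new one-letter amino acid (or \code{"*"}).
#' @return A \code{genetic_code} with \code{table_id = NA} and an amended name.
#' @export
derive_code <- function(base, reassignments) {
  stopifnot(inherits(base, "genetic_code"))
  bad <- setdiff(names(reassignments), names(base$codon_map))
  if (length(bad)) stop("not codons: ", paste(bad, collapse = ", "))
  badaa <- setdiff(reassignments, c(.AA_SYMBOLS, "*"))
  if (length(badaa)) stop("not amino-acid symbols: ", paste(badaa, collapse = ", "))
  map <- base$codon_map
  map[names(reassignments)] <- reassignments
  structure(
    list(table_id = NA_integer_,
         name = paste0(base$name, " + ",
                       paste(names(reassignments), "->", reassignments,
                             collapse = ", ")),
         codon_map = map, start_codons = base$start_codons),
    class = "genetic_code")
}

#' @export
print.genetic_code <- function(x, ...) {
  cat("Genetic code", if (!is.na(x$table_id)) paste0("table ", x$table_id)
      else "(derived)", "-", x$name, "\n")
  diffs <- code_diff(get_code(1), x)
  if (nrow(diffs) == 0L) {
    cat("  identical to the standard code\n")
  } else {
    cat("  differs from standard code at:",
        paste0(diffs$codon, " (", diffs$aa_a, "->", diffs$aa_b, ")",
               collapse = ", "), "\n")
  }
  invisible(x)
}

.split_codons <- function(seq) {
  n <- nchar(seq) %/% 3L
  if (n == 0L) return(character(0))
  substring(seq, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

#' Translate a coding sequence under a given code
#'
#' Translation is in the sequence's own frame 0; a trailing incomplete codon
#' is dropped. Codons containing any symbol other than A, C, G, T (ambiguity
#' codes, gaps, N) translate to \code{"X"}; stops are emitted as \code{"*"}.
#'
#' @param seq A single DNA string (T alphabet; case-insensitive).
#' @param code A \code{genetic_code}.
#' @return Amino-acid string of length \code{floor(nchar(seq)/3)}.
#' @examples
#' translate_cds("AGAAGG", get_code(13))  # "GG"
#' translate_cds("AGAAGG", get_code(5))   # "SS"
#' @export
translate_cds <- function(seq, code) {
  stopifnot(is.character(seq), length(seq) == 1L, inherits(code, "genetic_code"))
  codons <- .split_codons(toupper(seq))
  if (!length(codons)) return("")
  aa <- unname(code$codon_map[codons])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' Positions of stop codons under a code
#'
#' @param seq A single DNA string.
#' @param code A \code{genetic_code}.
#' @return Integer vector of 1-based codon positions translating to
#'   \code{"*"}; empty means the sequence reads through under that code.
#' @examples
#' stop_scan("ATGAGAGGT", get_code(2))   # codon 2 (AGA) is a stop
#' stop_scan("ATGAGAGGT", get_code(13))  # none
#' @export
stop_scan <- function(seq, code) {
  aa <- strsplit(translate_cds(seq, code), "")[[1]]
  which(aa == "*")
}

#' Tabulate assignment differences between two codes
#'
#' @param a,b \code{genetic_code} objects.
#' @return A data.frame with columns \code{codon}, \code{aa_a}, \code{aa_b},
#'   one row per codon assigned differently, sorted lexicographically by
#'   codon; zero rows when the codes agree everywhere.
#' @examples
#' code_diff(get_code(5), get_code(13))  # AGA/AGG: S vs G
#' @export
code_diff <- function(a, b) {
  stopifnot(inherits(a, "genetic_code"), inherits(b, "genetic_code"))
  codons <- sort(names(a$codon_map))
  aa_a <- unname(a$codon_map[codons])
  aa_b <- unname(b$codon_map[codons])
  keep <- aa_a != aa_b
  data.frame(codon = codons[keep], aa_a = aa_a[keep], aa_b = aa_b[keep],
             stringsAsFactors = FALSE)
}

#' Check whether two haplotype sequences differ only synonymously
#'
#' Compares two equal-length in-frame coding sequences codon by codon and
#' reports every differing codon with both translations, together with a flag
#' that is \code{TRUE} iff the two translations are identical.
#'
#' @param a,b DNA strings of equal length, both multiples of 3.
#' @param code A \code{genetic_code}.
#' @return List with \code{synonymous} (logical) and \code{differences}, a
#'   data.frame (\code{codon_pos}, \code{codon_a}, \code{codon_b},
#'   \code{aa_a}, \code{aa_b}) with one row per differing codon (1-based
#'   positions).
#' @export
is_synonymous_variant <- function(a, b, code) {
  a <- toupper(a); b <- toupper(b)
  if (nchar(a) != nchar(b))
    stop("sequences differ in length (", nchar(a), " vs ", nchar(b), ")")
  if (nchar(a) %% 3L != 0L)
    stop("sequence length ", nchar(a), " is not a multiple of 3")
  ca <- .split_codons(a); cb <- .split_codons(b)
  ta <- if (length(ca)) { x <- unname(code$codon_map[ca]); x[is.na(x)] <- "X"; x } else character(0)
  tb <- if (length(cb)) { x <- unname(code$codon_map[cb]); x[is.na(x)] <- "X"; x } else character(0)
  d <- which(ca != cb)
  list(
    synonymous = identical(ta, tb),
    differences = data.frame(codon_pos = d, codon_a = ca[d], codon_b = cb[d],
                             aa_a = ta[d], aa_b = tb[d],
                             stringsAsFactors = FALSE))
}

#' Export a code as a two-column codon/amino-acid TSV
#'
#' @param code A \code{genetic_code}.
#' @param path Output file path.
#' @return Invisibly, the path.
#' @export
write_code_tsv <- function(code, path) {
  df <- data.frame(codon = names(code$codon_map),
                   aa = unname(code$codon_map), stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
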
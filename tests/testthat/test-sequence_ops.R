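test_that("reverse complement is IUPAC-aware and an involution", {
  expect_identical(reverse_complement("ATGC"), "GCAT")
  expect_identical(reverse_complement(""), "")
  expect_identical(reverse_complement("ARN"), "NYT")
  expect_error(reverse_complement("ATQG"), "position 3")
  set.seed(5)
  for (i in 1:20) {
    s <- paste(sample(c("A", "C", "G", "T", "N", "R", "Y"), 30, TRUE),
               collapse = "")
    expect_identical(reverse_complement(reverse_complement(s)), s)
    expect_identical(reverse_complement(s), naive_revcomp(s))
  }
})

test_that("bracket region strings parse into 1-based specs with strand", {
  r <- parse_region("SCLE01415711.1[8054:6522]")
  expect_identical(r$accession, "SCLE01415711.1")
  expect_identical(r$start, 8054L)
  expect_identical(r$end, 6522L)
  expect_true(r$reverse)
  expect_false(parse_region("X[1:9]")$reverse)
  expect_error(parse_region("SCLE01415711.1(8054..6522)"), "cannot parse")
  expect_error(region_spec("x", 0, 5), ">= 1")
})

test_that("region extraction slices forward and reverse strands", {
  contig <- "AAACGTTT"
  expect_identical(as.character(extract_region(contig, region_spec("c", 4, 6))),
                   "CGT")
  expect_identical(as.character(extract_region(contig, region_spec("c", 6, 4))),
                   "ACG")  # reverse complement of CGT
  src <- attr(extract_region(contig, region_spec("c", 6, 4)), "source")
  expect_identical(src$strand, "-")
  expect_error(extract_region(contig, region_spec("c", 2, 9)), "exceeds")
})

test_that("extracted length is |start - end| + 1; reverse-strand gene spans 511 codons", {
  set.seed(9)
  contig <- random_dna(9000)
  for (i in 1:15) {
    a <- sample(9000, 1); b <- sample(9000, 1)
    out <- extract_region(contig, region_spec("c", a, b))
    expect_identical(nchar(out), abs(a - b) + 1L)
  }
  # the span convention applied to a reverse-strand gene region
  gene <- extract_region(random_dna(8100), region_spec("acc", 8054, 6522))
  expect_identical(nchar(gene), 1533L)        # 8054 - 6522 + 1
  expect_identical(nchar(gene) %/% 3L, 511L)  # codon count
})

test_that("reverse-strand extraction is consistent with manual complementation", {
  set.seed(13)
  contig <- random_dna(300)
  a <- 250; b <- 101
  rev_region <- extract_region(contig, region_spec("c", a, b))
  fwd_region <- extract_region(contig, region_spec("c", b, a))
  expect_identical(as.character(rev_region), naive_revcomp(fwd_region))
  expect_identical(translate_cds(rev_region, get_code(13)),
                   translate_cds(naive_revcomp(fwd_region), get_code(13)))
})

test_that("circular contigs allow regions wrapping the origin", {
  contig <- "AAACGTTT"
  wrapped <- extract_region(contig, region_spec("c", 7, 10), circular = TRUE)
  expect_identical(as.character(wrapped), "TTAA")
  expect_error(extract_region(contig, region_spec("c", 7, 10)), "exceeds")
})

test_that("FASTA files round-trip through the readers and writers", {
  seqs <- c(one = random_dna(130), two = random_dna(61), empty = "")
  path <- withr::local_tempfile(fileext = ".fa")
  write_fasta(seqs, path)
  expect_identical(read_fasta(path)[c("one", "two")], seqs[c("one", "two")])
})

test_that("majority consensus picks column majorities and flags ties", {
  same <- c(a = "ATGC", b = "ATGC", c = "ATGC")
  cons <- majority_consensus(same)
  expect_identical(cons$sequence, "ATGC")
  expect_true(all(cons$support$agreeing == 3L))
  expect_true(all(cons$support$coverage == 3L))

  frags <- c(a = "ATG", b = "ATG", c = "GTG")
  cons2 <- majority_consensus(frags)
  expect_identical(cons2$sequence, "ATG")
  expect_identical(cons2$support$agreeing[1], 2L)

  tie <- c(a = "A-", b = "G-")  # all-gap column dropped, A<G tie order
  cons3 <- majority_consensus(tie)
  expect_identical(cons3$sequence, "A")
  expect_true(cons3$support$tie[1])

  expect_error(majority_consensus(character(0)), "empty")
  expect_error(majority_consensus(c(a = "AT", b = "ATG")), "equal length")
})

test_that("consensus matches an independent column census on random fragment sets", {
  set.seed(21)
  order_rank <- c(A = 1, C = 2, G = 3, T = 4, N = 5)
  for (rep in 1:10) {
    n <- sample(3:7, 1); w <- sample(10:25, 1)
    m <- matrix(sample(c("A", "C", "G", "T", "N", "-"), n * w, TRUE,
                       prob = c(rep(0.18, 5), 0.1)), n, w)
    frags <- setNames(apply(m, 1, paste, collapse = ""), paste0("f", 1:n))
    cons <- majority_consensus(frags)
    expected <- character(0)
    for (j in seq_len(w)) {
      col <- m[, j][m[, j] != "-"]
      if (!length(col)) next
      tab <- table(col)
      winners <- names(tab)[tab == max(tab)]
      expected <- c(expected, winners[order(order_rank[winners])][1])
    }
    expect_identical(cons$sequence, paste(expected, collapse = ""))
  }
})

test_that("a clear majority beats a minority of discordant fragments", {
  truth <- random_dna(40)
  frags <- c(setNames(rep(truth, 5), paste0("t", 1:5)),
             noisy1 = random_dna(40), noisy2 = random_dna(40))
  expect_identical(majority_consensus(frags)$sequence, truth)
})

test_that("haplotype grouping follows the transitive compatibility closure", {
  expect_length(group_haplotypes(c(a = "ATG", b = "ATG", c = "ATG")), 1L)

  # two blocks differing at one shared variable column
  two <- c(a = "ATG", b = "ATG", c = "ACG", d = "ACG")
  groups <- group_haplotypes(two)
  expect_length(groups, 2L)
  expect_setequal(groups[[which(vapply(groups, function(g) "a" %in% g, TRUE))]],
                  c("a", "b"))

  # fragments that never overlap join through an intermediate
  linked <- c(x = "AT--", y = "ATGC", z = "--GC")
  expect_length(group_haplotypes(linked), 1L)
})

test_that("haplotype partition equals the brute-force pairwise closure and ignores order", {
  set.seed(33)
  for (rep in 1:8) {
    m <- matrix(sample(c("A", "G", "-"), 6 * 12, TRUE, prob = c(0.45, 0.35, 0.2)),
                6, 12)
    frags <- setNames(apply(m, 1, paste, collapse = ""), paste0("f", 1:6))
    groups <- group_haplotypes(frags)

    # independent oracle: pairwise compatibility + closure via matrix powers
    var_cols <- which(apply(m, 2, function(cl) length(unique(cl[cl != "-"])) > 1))
    compat <- diag(6) > 0
    for (i in 1:6) for (j in 1:6) {
      both <- var_cols[m[i, var_cols] != "-" & m[j, var_cols] != "-"]
      compat[i, j] <- all(m[i, both] == m[j, both])
    }
    reach <- compat
    for (k in 1:6) reach <- (reach %*% compat) > 0
    oracle_partition <- unique(apply(reach, 1, function(r) paste(which(r), collapse = ",")))
    got_partition <- vapply(groups, function(g)
      paste(sort(match(g, names(frags))), collapse = ","), character(1))
    expect_setequal(got_partition, oracle_partition)

    perm <- sample(6)
    groups_perm <- group_haplotypes(frags[perm])
    expect_setequal(vapply(groups_perm, function(g) paste(sort(g), collapse = ","),
                           character(1)),
                    vapply(groups, function(g) paste(sort(g), collapse = ","),
                           character(1)))
  }
})
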
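test_that("conservation rules validate their parameters", {
  expect_error(conservation_rule(-1), "max_mismatch")
  expect_error(conservation_rule(1, focal_groups = list(c("a", "b"), c("b", "c"))),
               "disjoint")
})

test_that("the relaxed rule tolerates one mismatching unit, the strict rule none", {
  rec <- data.frame(species = c("f", paste0("s", 1:6)),
                    aa = c("M", "I", "I", "I", "I", "I", "I"))
  expect_identical(conserved_for(rec, "f", conservation_rule(0)), "I")

  rec$aa[7] <- "V"  # one of six non-focal units deviates
  expect_identical(conserved_for(rec, "f", conservation_rule(1)), "I")
  expect_true(is.na(conserved_for(rec, "f", conservation_rule(0))))
  expect_error(conserved_for(rec, "zz", conservation_rule(1)), "not in column")
})

test_that("grouped sister species vote as a single unit and are excluded with the focal", {
  rule <- conservation_rule(1, focal_groups = list(c("p1", "p2")))
  rec <- data.frame(species = c("p1", "p2", "s1", "s2", "s3"),
                    aa = c("M", "M", "I", "I", "I"))
  # focal p1: partner p2 is excluded too, so the vote is a clean 3 x Ile
  expect_identical(conserved_for(rec, "p1", rule), "I")
  expect_identical(conserved_for(rec, "p1", conservation_rule(0, list(c("p1", "p2")))),
                   "I")
  # with partner_votes the partner's Met counts as the single mismatch
  rule_pv <- conservation_rule(1, focal_groups = list(c("p1", "p2")),
                               partner_votes = TRUE)
  expect_identical(conserved_for(rec, "p1", rule_pv), "I")
  expect_true(is.na(conserved_for(
    rec, "p1", conservation_rule(0, list(c("p1", "p2")), partner_votes = TRUE))))
  # focal outside the group: the pair collapses to one mismatching unit
  expect_identical(conserved_for(rec, "s1", rule), "I")
})

test_that("conserved_for matches exhaustive enumeration over 5-unit vote patterns", {
  symbols <- c("I", "V", "L", "-")
  grid <- expand.grid(rep(list(symbols), 5), stringsAsFactors = FALSE)
  for (mm in 0:1) for (gaps in c(FALSE, TRUE)) {
    rule <- conservation_rule(mm, count_gaps_as_mismatch = gaps)
    for (r in seq_len(nrow(grid))) {
      states <- unlist(grid[r, ], use.names = FALSE)
      rec <- data.frame(species = c("f", paste0("s", 1:5)),
                        aa = c("A", states))
      expect_identical(conserved_for(rec, "f", rule),
                       oracle_conserved(states, mm, gaps),
                       label = paste(c(states, mm, gaps), collapse = " "))
    }
  }
})

test_that("grouped-unit collapsing matches the enumeration oracle", {
  symbols <- c("I", "V", "-")
  grid <- expand.grid(rep(list(symbols), 5), stringsAsFactors = FALSE)
  rule <- conservation_rule(1, focal_groups = list(c("g1", "g2")))
  for (r in seq_len(nrow(grid))) {
    v <- unlist(grid[r, ], use.names = FALSE)
    rec <- data.frame(species = c("f", "g1", "g2", "s1", "s2", "s3"),
                      aa = c("A", v))
    states <- c(oracle_unit_state(v[1:2]), v[3:5])
    expect_identical(conserved_for(rec, "f", rule),
                     oracle_conserved(states, 1, FALSE))
  }
})

test_that("strict conservation implies relaxed conservation with the same residue", {
  set.seed(41)
  for (rep in 1:200) {
    rec <- data.frame(species = c("f", paste0("s", 1:7)),
                      aa = sample(c("I", "V", "M", "-"), 8, TRUE,
                                  prob = c(0.5, 0.2, 0.2, 0.1)))
    strict <- conserved_for(rec, "f", conservation_rule(0))
    if (!is.na(strict))
      expect_identical(conserved_for(rec, "f", conservation_rule(1)), strict)
  }
})

test_that("conservation calls are invariant to species order", {
  set.seed(43)
  rule <- conservation_rule(1, focal_groups = list(c("s2", "s3")))
  for (rep in 1:50) {
    rec <- data.frame(species = c("f", paste0("s", 1:6)),
                      aa = sample(c("I", "V", "-"), 7, TRUE))
    got <- conserved_for(rec, "f", rule)
    perm <- rec[sample(nrow(rec)), ]
    expect_identical(conserved_for(perm, "f", rule), got)
  }
})

test_that("context tables count planted codons at conserved columns exactly", {
  w <- 100
  others <- paste0("s", 1:6)
  aa_f <- rep("I", w); codon_f <- rep("ATT", w)
  aa_o <- rep("I", w); codon_o <- rep("ATC", w)
  # columns 1-4: focal ATA over conserved Ile; 5-6: focal ATA over conserved Met
  aa_f[1:6] <- "M"; codon_f[1:6] <- "ATA"
  aa_mat <- list(f = paste(aa_f, collapse = ""))
  codon_mat <- list(f = codon_f)
  for (sp in others) {
    a <- aa_o; cd <- codon_o
    a[5:6] <- "M"; cd[5:6] <- "ATG"
    aa_mat[[sp]] <- paste(a, collapse = "")
    codon_mat[[sp]] <- cd
  }
  ca <- make_alignment(setNames(unlist(aa_mat), names(aa_mat)), codon_mat)
  tab <- codon_context_table(ca, "f", c("ATA", "ATC", "ATG", "ATT"),
                             c("M", "I"), conservation_rule(1))
  expect_identical(unname(tab$totals["ATA"]), 6L)
  expect_identical(unname(tab$totals["ATT"]), 94L)
  expect_identical(tab$context_counts["ATA", "I"], 4L)
  expect_identical(tab$context_counts["ATA", "M"], 2L)
  expect_identical(tab$context_counts["ATT", "I"], 94L)
  # marginal: context counts never exceed totals
  expect_true(all(rowSums(tab$context_counts) <= tab$totals))
})

test_that("a focal species that never uses a codon yields a zero row", {
  ca <- make_alignment(
    c(f = "III", s1 = "III", s2 = "III"),
    list(f = c("ATT", "ATC", "ATT"), s1 = rep("ATT", 3), s2 = rep("ATC", 3)))
  tab <- codon_context_table(ca, "f", c("ATA", "ATC", "ATG", "ATT"),
                             c("M", "I"), conservation_rule(1))
  expect_identical(unname(tab$totals["ATA"]), 0L)
  expect_identical(unname(tab$context_counts["ATA", ]), c(0L, 0L))
})

test_that("identical translated rows make every column conserved with context = total", {
  cds <- "ATGATAGGATGG"
  species <- paste0("s", 1:4)
  ca <- codon_alignment_from_cds(setNames(rep(cds, 4), species), get_code(13))
  tab <- codon_context_table(ca, "s1", c("ATA", "ATC", "ATG", "ATT"),
                             c("M", "I"), conservation_rule(0))
  expect_identical(tab$context_counts["ATA", "M"], unname(tab$totals["ATA"]))
  expect_identical(tab$context_counts["ATG", "M"], unname(tab$totals["ATG"]))
})

test_that("context-table counts are invariant to row order of the alignment", {
  set.seed(47)
  ds <- simulate_dataset(sim_config(n_columns = 80, seed = 5))
  ca <- codon_alignment_from_cds(ds$cds_by_species, get_code(13))
  rule <- conservation_rule(1, focal_groups = list(sim_focal_pair()))
  tab <- codon_context_table(ca, "app_odioica", c("ATA", "ATC", "ATG", "ATT"),
                             c("M", "I"), rule)
  perm <- sample(length(ca$species))
  ca_perm <- make_alignment(
    setNames(apply(ca$aa, 1, paste, collapse = "")[perm], ca$species[perm]),
    setNames(lapply(perm, function(i) ca$cells[i, ]), ca$species[perm]))
  tab2 <- codon_context_table(ca_perm, "app_odioica",
                              c("ATA", "ATC", "ATG", "ATT"), c("M", "I"), rule)
  expect_identical(tab$totals, tab2$totals)
  expect_identical(tab$context_counts, tab2$context_counts)
})

test_that("shared conserved-column scan reports exactly the planted AGR glycines", {
  w <- 50
  planted <- c(3L, 9L, 14L, 22L, 30L, 41L, 47L)
  species <- c("t1", "t2", "t3", "t4")
  aa_mat <- list(); codon_mat <- list()
  for (sp in species) {
    aa <- rep("L", w); cd <- rep("CTT", w)
    aa[planted] <- "G"; cd[planted] <- "GGA"
    aa_mat[[sp]] <- paste(aa, collapse = ""); codon_mat[[sp]] <- cd
  }
  codon_mat$t2[planted] <- "AGA"  # one tunicate uses AGR at the Gly columns
  ca <- make_alignment(setNames(unlist(aa_mat), species), codon_mat)
  hits <- shared_conserved_codon_columns(ca, "G", c("AGA", "AGG"),
                                         conservation_rule(1))
  expect_identical(sort(unique(hits$column)), planted)
  expect_true(all(hits$species == "t2"))

  none <- shared_conserved_codon_columns(ca, "W", c("TGA"), conservation_rule(1))
  expect_identical(nrow(none), 0L)
})

test_that("per-focal tables combine into the published wide layout", {
  ca <- make_alignment(
    c(f = "III", g = "III", s1 = "III", s2 = "III"),
    list(f = c("ATT", "ATC", "ATT"), g = rep("ATT", 3),
         s1 = rep("ATT", 3), s2 = rep("ATC", 3)))
  rule <- conservation_rule(1)
  tabs <- lapply(c("f", "g"), function(sp)
    codon_context_table(ca, sp, c("ATA", "ATC", "ATG", "ATT"), c("M", "I"), rule))
  wide <- context_tables_wide(tabs)
  expect_identical(names(wide), c("row", "f", "g"))
  expect_true("ATA number" %in% wide$row)
  expect_true("ATA on cons. M" %in% wide$row)
  expect_identical(wide$f[wide$row == "ATT number"], 2L)
})
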
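test_that("primer sites: exact hits, threshold, IUPAC and N handling", {
  set.seed(61)
  # non-palindromic 16-mer so plus and minus strands are distinguishable
  primer <- "TGGATCGTTAGCCAAG"
  bg <- paste(sample(c("A", "C", "G", "T"), 500, replace = TRUE),
              collapse = "")
  asm <- genome_assembly(c(s1 = paste0(bg, primer, bg)))
  hits <- find_primer_sites(asm, primer, max_mismatch = 0)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$start, 500L)
  expect_equal(hits$strand, "+")
  expect_equal(hits$mismatches, 0L)

  # a reverse-complemented copy is found on the minus strand
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(primer)))
  asm_rc <- genome_assembly(c(s1 = paste0(bg, rc, bg)))
  hits_rc <- find_primer_sites(asm_rc, primer, max_mismatch = 0)
  expect_equal(hits_rc$strand, "-")
  expect_equal(hits_rc$start, 500L)

  # 5 substitutions exceed the allowance of 4
  bad <- primer
  substr(bad, 1, 5) <- "ACTGA"               # flips 5 of the 16 positions
  expect_equal(sum(strsplit(bad, "")[[1]] != strsplit(primer, "")[[1]]), 5L)
  asm2 <- genome_assembly(c(s1 = paste0(bg, bad, bg)))
  expect_equal(nrow(find_primer_sites(asm2, primer, 4)), 0L)

  # IUPAC in the primer matches its expansion; genome N never matches
  asm3 <- genome_assembly(c(s1 = "GGGGACGAGGGG"))
  expect_equal(find_primer_sites(asm3, "GGGGACGRGG", 0)$start, 0L)
  asm4 <- genome_assembly(c(s1 = "GGGGACGNGGGG"))
  expect_equal(nrow(find_primer_sites(asm4, "GGGGACGAGG", 0)), 0L)
  expect_equal(find_primer_sites(asm4, "GGGGACGAGG", 1)$mismatches, 1L)

  expect_error(find_primer_sites(asm3, "ACGTXXGT"), "IUPAC")
})

test_that("site finder equals the exhaustive Hamming oracle", {
  set.seed(62)
  for (rep_ in 1:3) {
    seqs <- list(g1 = paste(sample(c("A", "C", "G", "T", "N"), 3000,
                                   replace = TRUE,
                                   prob = c(.24, .24, .24, .24, .04)),
                            collapse = ""))
    primer <- paste(sample(c("A", "C", "G", "T", "R", "Y"), 10,
                           replace = TRUE, prob = c(.23, .23, .23, .23, .04, .04)),
                    collapse = "")
    asm <- genome_assembly(unlist(seqs))
    got <- as.data.frame(find_primer_sites(asm, primer, 3))
    want <- hamming_sites_oracle(seqs, primer, 3)
    rownames(got) <- rownames(want) <- NULL
    got <- got[order(got$start, got$strand), ]
    want <- want[order(want$start, want$strand), ]
    expect_equal(got$start, want$start)
    expect_equal(got$mismatches, want$mismatches)
    expect_equal(got$strand, want$strand)
  }
})

test_that("amplicon pairing enforces facing orientation and span bounds", {
  fwd <- data.table::data.table(scaffold = "s", start = 100L, end = 120L,
                                strand = "+", mismatches = 1L)
  rev <- data.table::data.table(scaffold = "s", start = 329L, end = 349L,
                                strand = "-", mismatches = 2L)
  amp <- pair_amplicons(fwd, rev)
  expect_equal(nrow(amp), 1L)
  expect_equal(amp$length, 249L)
  expect_equal(amp$orientation, "FR")
  expect_equal(amp$fwd_mm, 1L)
  expect_equal(amp$rev_mm, 2L)
  expect_equal(amp$mm_score, 2L)
  expect_equal(amp$tm_score, 3L)
  expect_false(amp$single_primer)

  # span of 1001 is out of bounds
  rev2 <- data.table::copy(rev)[, `:=`(start = 1081L, end = 1101L)]
  expect_equal(nrow(pair_amplicons(fwd, rev2)), 0L)

  # same-primer facing product is emitted but flagged
  fwd2 <- rbind(fwd, data.table::data.table(scaffold = "s", start = 300L,
                                            end = 320L, strand = "-",
                                            mismatches = 0L))
  amp2 <- pair_amplicons(fwd2, rev[0])
  expect_equal(amp2$orientation, "FF")
  expect_true(amp2$single_primer)

  # RF: reverse primer upstream
  amp3 <- pair_amplicons(fwd2[2][, strand := "-"][, start := 400L][, end := 420L],
                         rev[, `:=`(strand = "+", start = 100L, end = 120L)])
  expect_equal(amp3$orientation, "RF")
})

test_that("ranking is ascending by MM, TM, length and stable", {
  amps <- data.table::data.table(
    scaffold = "s", start = 1:4, end = 2:5,
    length = c(300L, 120L, 200L, 200L),
    orientation = "FR",
    fwd_mm = c(1L, 3L, 1L, 1L), rev_mm = c(1L, 0L, 3L, 3L),
    mm_score = c(1L, 3L, 3L, 3L), tm_score = c(2L, 3L, 4L, 4L),
    single_primer = FALSE)
  ranked <- rank_amplicons(amps)
  expect_equal(ranked$mm_score[1], 1L)        # MM primary
  expect_equal(ranked$tm_score[2], 3L)        # then TM
  # full tie keeps input order (stability): rows 3 and 4 tie on all keys
  expect_equal(ranked$start[3:4], c(3L, 4L))
})

test_that("classification implements the NA/D/L rules", {
  amp <- function(mm_f, mm_r, len = 300L, ori = "FR") {
    data.table::data.table(scaffold = "s", start = 0L, end = len,
                           length = len, orientation = ori,
                           fwd_mm = mm_f, rev_mm = mm_r,
                           mm_score = max(mm_f, mm_r),
                           tm_score = mm_f + mm_r,
                           single_primer = !ori %in% c("FR", "RF"))
  }
  expect_equal(classify_marker("m", chromdiv:::empty_amplicons())$category, "NA")

  c1 <- classify_marker("m", amp(2L, 1L))
  expect_equal(c1$category, "L"); expect_equal(c1$group, 1L)

  # group 2 via MM separation
  c2 <- classify_marker("m", rbind(amp(1L, 0L), amp(3L, 2L)))
  expect_equal(c2$category, "L"); expect_equal(c2$group, 2L)
  # group 2 via TM separation
  c2b <- classify_marker("m", rbind(amp(1L, 1L), amp(2L, 3L)))
  expect_equal(c2b$category, "L"); expect_equal(c2b$group, 2L)
  # separation failure: dMM = 1, dTM = 1 -> declined
  c3 <- classify_marker("m", rbind(amp(1L, 1L), amp(2L, 1L)))
  expect_equal(c3$category, "D")
  # MM 4 top -> declined even when unique
  expect_equal(classify_marker("m", amp(4L, 0L))$category, "D")
  # single-primer top -> declined, never localized
  expect_equal(classify_marker("m", amp(0L, 0L, ori = "FF"))$category, "D")
})

test_that("marker categories are strand-symmetric", {
  cfg <- test_config(seed = 63, autosome_length = 1e5, x_length = 1.5e5)
  g <- simulate_genome(cfg)
  ps <- simulate_panel(cfg, g)
  fwdcat <- marker_table(str_map(ps$genome, ps$panel))$category
  rc <- genome_assembly(setNames(
    as.character(Biostrings::reverseComplement(ps$genome$seq)),
    ps$genome$ids))
  revcat <- marker_table(str_map(rc, ps$panel))$category
  expect_equal(fwdcat, revcat)
})

test_that("every marker lands in exactly one category", {
  cfg <- test_config(seed = 64, autosome_length = 2e5, x_length = 1.5e5)
  g <- simulate_genome(cfg)
  ps <- simulate_panel(cfg, g)
  tab <- marker_table(str_map(ps$genome, ps$panel))
  expect_equal(nrow(tab), nrow(ps$panel))
  expect_true(all(tab$category %in% c("NA", "D", "L")))
  expect_equal(sum(tab$category == "NA") + sum(tab$category == "D") +
                 sum(tab$category == "L"), nrow(ps$panel))
})

test_that("panel report computes densities and chromosome labeling", {
  # density arithmetic on published-style counts: 30 L markers across a
  # 19-chromosome karyotype, 13 of them labeled
  d <- str_densities(30, 19, 13)
  expect_equal(d$overall_density, 30 / 19, tolerance = 1e-12)
  expect_equal(d$labeled_density, 30 / 13, tolerance = 1e-12)

  cfg <- test_config(seed = 65, autosome_length = 2e5, x_length = 1.5e5)
  g <- simulate_genome(cfg)
  ps <- simulate_panel(cfg, g)
  calls <- str_map(ps$genome, ps$panel)
  rep_ <- panel_report(calls, ps$genome, n_chromosomes = 3L)
  expect_equal(rep_$n_localized + rep_$n_not_amplified + rep_$n_declined,
               nrow(ps$panel))
  expect_equal(rep_$n_chrom_with_markers + rep_$n_chrom_without_markers, 3L)
  expect_equal(rep_$overall_density, rep_$n_localized / 3)
  expect_error(panel_report(calls, ps$genome, 99L), "exceeds")

  # all-NA panel: zero densities, no labeled chromosomes
  calls_na <- list(classify_marker("x", chromdiv:::empty_amplicons()))
  rep0 <- panel_report(calls_na, ps$genome, 3L)
  expect_equal(rep0$overall_density, 0)
  expect_equal(rep0$n_chrom_with_markers, 0L)
})

test_that("primer panel reader validates input", {
  p <- tempfile(fileext = ".tsv")
  writeLines(c("marker_id\tforward\treverse\tsource",
               "mk1\tACGTACGTACGT\tTTGCATGCATGC\tsynthetic"), p)
  panel <- read_primer_panel(p)
  expect_equal(panel$marker_id, "mk1")
  writeLines(c("marker_id\tforward\treverse",
               "mk1\tACGTACGTACGT\tTTGCATGCATGC",
               "mk1\tACGTACGTACGT\tTTGCATGCATGC"), p)
  expect_error(read_primer_panel(p), "duplicate")
  writeLines(c("marker_id\tforward\treverse", "mk1\tACGT\tTTGCATGCATGC"), p)
  expect_error(read_primer_panel(p), "shorter")
})
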
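test_that("generation is byte-deterministic under a fixed seed", {
  cfg <- test_config(seed = 71)
  run_once <- function() {
    g <- simulate_genome(cfg)
    v <- simulate_variants(cfg, g, "male")
    d <- simulate_depth(cfg, g, "male")
    fa <- tempfile(fileext = ".fa"); write_fasta(g$chromosome, fa)
    vcf <- tempfile(fileext = ".vcf")
    write_sim_vcf(v$records, scaffold_lengths(g$chromosome), vcf)
    bg <- tempfile(fileext = ".bedgraph"); write_bedgraph(d, bg)
    list(fa = readBin(fa, "raw", file.size(fa)),
         vcf = readBin(vcf, "raw", file.size(vcf)),
         bg = readBin(bg, "raw", file.size(bg)))
  }
  a <- run_once(); b <- run_once()
  expect_identical(a$fa, b$fa)
  expect_identical(a$vcf, b$vcf)
  expect_identical(a$bg, b$bg)
})

test_that("the draft conserves sequence content and hits its N50 target", {
  lens_ok <- vapply(1:12, function(s) {
    cfg <- test_config(seed = 100 + s)
    g <- simulate_genome(cfg)
    mc <- compute_assembly_metrics(g$chromosome)
    md <- compute_assembly_metrics(g$draft)
    # non-N draft content equals the chromosome-level sequence exactly
    expect_equal(md$total_length - md$gap_length,
                 mc$total_length - mc$gap_length)
    md$scaffold_n50
  }, 0)
  # fragmentation lands near the requested N50 on average, each draft
  # within a generous band
  expect_lt(abs(mean(lens_ok) - 5e4) / 5e4, 0.2)
  expect_true(all(lens_ok > 5e4 * 0.4 & lens_ok < 5e4 * 2.5))
})

test_that("fragment map tiles the chromosomes and lifts SNPs exactly", {
  cfg <- test_config(seed = 73)
  g <- simulate_genome(cfg)
  fm <- g$truth$fragments
  lens <- scaffold_lengths(g$chromosome)
  for (id in names(lens)) {
    f <- fm[fm$chrom == id]
    expect_equal(min(f$chrom_start), 0)
    expect_equal(max(f$chrom_end), unname(lens[[id]]))
    expect_equal(sum(f$chrom_end - f$chrom_start), unname(lens[[id]]))
  }
  # draft het-SNP count equals chromosome-level count (same planted set)
  v <- simulate_variants(cfg, g, "female")
  het <- v$records[v$records$is_snp & v$records$is_het]
  idx <- fm[het, on = .(chrom = scaffold, chrom_start < pos, chrom_end >= pos)]
  expect_equal(nrow(idx), nrow(het))           # no duplicate assignment
  expect_false(anyNA(idx$draft_scaffold))      # every SNP lands in a fragment
})

test_that("field-violation fractions match the configured rate", {
  cfg <- test_config(seed = 74, autosome_length = 2e6)
  g <- simulate_genome(cfg)
  v <- simulate_variants(cfg, g, "female")
  n <- nrow(v$records)
  for (col in c("qual", "gq")) {
    frac <- mean(v$records[[col]] < 20)
    expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / n) + 1e-3)
  }
  expect_lt(abs(mean(v$records$sp > 60) - 0.05),
            3 * sqrt(0.05 * 0.95 / n) + 1e-3)
  expect_lt(abs(mean(v$records$dp < 5) - 0.05),
            3 * sqrt(0.05 * 0.95 / n) + 1e-3)
})

test_that("the hemizygous male X body carries no variants", {
  cfg <- test_config(seed = 75)
  g <- simulate_genome(cfg)
  v <- simulate_variants(cfg, g, "male")
  body_end <- cfg$x_length - cfg$par_length
  on_body <- v$records$scaffold == "chrX" & v$records$pos <= body_end
  expect_equal(sum(on_body), 0L)
  # but the PAR is populated
  expect_gt(sum(v$records$scaffold == "chrX"), 0L)
})

test_that("male depth separates X body and PAR into the expected bands", {
  cfg <- test_config(seed = 76)
  g <- simulate_genome(cfg)
  d <- simulate_depth(cfg, g, "male")
  prof <- window_median_depth(d, 1e4, scaffolds = "chrX")
  body <- prof[prof$end <= cfg$x_length - cfg$par_length]
  par_win <- prof[prof$start >= cfg$x_length - cfg$par_length]
  expect_gt(mean(body$band == "half"), 0.95)
  expect_gt(mean(par_win$band == "full"), 0.95)

  # female X is indistinguishable from autosomes
  df <- simulate_depth(cfg, g, "female")
  proff <- window_median_depth(df, 1e4)
  expect_true(all(proff$band == "full"))
})

test_that("disabling noise yields an exact step function", {
  cfg <- test_config(seed = 77, depth_noise = "none")
  g <- simulate_genome(cfg)
  d <- simulate_depth(cfg, g, "male")
  x <- scaffold_depth(d, "chrX")
  body_end <- cfg$x_length - cfg$par_length
  expect_true(all(x[1:body_end] == cfg$mean_depth / 2))
  expect_true(all(x[(body_end + 1):cfg$x_length] == cfg$mean_depth))
  expect_true(all(scaffold_depth(d, "auto1") == cfg$mean_depth))
})

test_that("window-level depth sampler matches the per-base law", {
  set.seed(78)
  # autosomes dominate the genome so the X body cannot drag the median
  prof <- simulate_depth_profile(x_length = 1e6, par_length = 3e5,
                                 autosome_bases = 1e7, mean_depth = 30)
  expect_equal(length(prof$medians), 100L)
  # Poisson(30) has CDF(29) ~ 0.476, so even a small half-depth admixture
  # can tip the genome-wide median to 29
  expect_lte(abs(prof$genome_median - 30), 1)
  body <- prof$medians[prof$ends <= prof$par_start]
  parm <- prof$medians[prof$starts >= prof$par_start]
  expect_lt(max(abs(body - 15)), 2)
  expect_lt(max(abs(parm - 30)), 2)
})

test_that("planted panel truth is recovered by the classifier", {
  cfg <- test_config(seed = 79, autosome_length = 2e5, x_length = 1.5e5)
  g <- simulate_genome(cfg)
  ps <- simulate_panel(cfg, g)
  tab <- marker_table(str_map(ps$genome, ps$panel))
  merged <- merge(tab, ps$truth, by = "marker_id", suffixes = c("", ".true"))
  expect_equal(merged$category, merged$category.true)
  expect_equal(merged$group, merged$group.true)
})
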
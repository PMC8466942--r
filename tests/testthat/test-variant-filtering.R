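make_vcf <- function(rows, path = tempfile(fileext = ".vcf"),
                     format = "GT:DP:GQ:SP") {
  hdr <- c("##fileformat=VCFv4.2",
           "##contig=<ID=s1,length=10000>",
           "##contig=<ID=s2,length=10000>",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"g\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"d\">",
           "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"q\">",
           "##FORMAT=<ID=SP,Number=1,Type=Integer,Description=\"s\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tsmp")
  writeLines(c(hdr, rows), path)
  path
}

test_that("read_vcf parses records and surfaces missing FORMAT values", {
  p <- make_vcf(c("s1\t5\t.\tA\tT\t50\t.\t.\tGT:DP:GQ:SP\t0/1:30:99:5",
                  "s1\t9\t.\tA\tT,G\t50\t.\t.\tGT:DP:GQ:SP\t1/2:30:99:5"))
  rec <- read_vcf(p)
  expect_equal(nrow(rec), 2L)
  expect_equal(rec$pos, c(5L, 9L))
  expect_equal(rec$n_alt, c(1L, 2L))           # multi-allelic ALT kept as list
  expect_equal(rec$alt[2], "T,G")
  expect_equal(attr(rec, "skipped"), 0L)

  # record with GQ missing is excluded and tallied, not zero-filled
  p2 <- make_vcf(c("s1\t5\t.\tA\tT\t50\t.\t.\tGT:DP:GQ:SP\t0/1:30:99:5",
                   "s1\t9\t.\tA\tT\t50\t.\t.\tGT:DP:SP\t0/1:30:5"))
  expect_warning(rec2 <- read_vcf(p2), "excluded")
  expect_equal(nrow(rec2), 1L)
  expect_equal(attr(rec2, "skipped"), 1L)
})

test_that("quality filter drops on any threshold violation, boundaries keep", {
  rec <- data.table::data.table(
    qual = c(19.9, 20.0, 50, 50, 50),
    sp   = c(0,    60.0, 61, 30, 30),
    dp   = c(30,   5.0,  30, 4,  30),
    gq   = c(99,   20.0, 99, 99, 19))
  expect_equal(quality_filter(rec), c(FALSE, TRUE, FALSE, FALSE, FALSE))
})

test_that("coverage mask marks maximal in-band runs, inclusive at both ends", {
  tr <- depth_track(list(s1 = c(30, 30, 5, 30)))
  m <- build_coverage_mask(tr, genome_median = 30)
  expect_equal(m$start, c(0, 3))
  expect_equal(m$end, c(2, 4))

  # all at median: one full-length interval
  tr2 <- depth_track(list(s1 = rep(20, 50)))
  m2 <- build_coverage_mask(tr2)
  expect_equal(as.list(m2[, .(start, end)]), list(start = 0, end = 50))

  # 250% boundary is retained
  tr3 <- depth_track(list(s1 = c(30, 75, 76)))
  m3 <- build_coverage_mask(tr3, genome_median = 30)
  expect_equal(m3$end, 2)
  expect_error(build_coverage_mask(tr3, genome_median = 0), "positive")
})

test_that("apply_mask uses half-open 0-based membership", {
  rec <- data.table::data.table(scaffold = "s1", pos = c(1L, 2L, 3L))
  mask <- build_coverage_mask(depth_track(list(s1 = c(10, 10, 1))),
                              genome_median = 10)
  kept <- apply_mask(rec, mask)
  expect_equal(kept$pos, c(1L, 2L))            # pos=3 -> 0-based 2, outside
  expect_equal(attr(kept, "dropped"), 1L)

  empty <- mask[0]
  kept0 <- apply_mask(rec, empty)
  expect_equal(nrow(kept0), 0L)
  expect_equal(attr(kept0, "dropped"), 3L)

  # scaffold absent from mask: dropped and counted
  rec2 <- data.table::data.table(scaffold = c("s1", "s9"), pos = c(1L, 1L))
  kept2 <- apply_mask(rec2, mask)
  expect_equal(kept2$scaffold, "s1")
  expect_equal(attr(kept2, "dropped"), 1L)
})

test_that("SNP/indel split sends mixed multi-allelics to the indel bucket", {
  rec <- data.table::data.table(ref = c("A", "A", "A", "AT"),
                                alt = c("T", "AT", "T,AT", "A"))
  sp <- split_snp_indel(rec)
  expect_equal(sp$snps$alt, "T")
  expect_equal(nrow(sp$indels), 3L)
  expect_equal(nrow(sp$snps) + nrow(sp$indels), nrow(rec))
})

test_that("heterozygosity requires two distinct alleles", {
  expect_equal(is_het(c("0/1", "1/1", "0|1", "1/2", "0/0")),
               c(TRUE, FALSE, TRUE, TRUE, FALSE))
})

test_that("filter agrees with brute-force re-evaluation and is idempotent", {
  cfg <- test_config(seed = 21)
  g <- simulate_genome(cfg)
  v <- simulate_variants(cfg, g, "female")
  rec <- v$records
  # brute force: the literal boolean expression per record
  brute <- !(rec$qual < 20.0 | rec$sp > 60.0 | rec$dp < 5.0 | rec$gq < 20.0)
  keep <- quality_filter(rec)
  expect_identical(keep, brute)
  expect_identical(keep, rec$pass_quality)     # generator truth agrees
  # idempotent: filtering the kept stream changes nothing
  expect_true(all(quality_filter(rec[keep])))
  # no silent loss
  expect_equal(sum(keep) + sum(!keep), nrow(rec))
})

test_that("end-to-end VCF filtering writes a readable filtered VCF", {
  cfg <- test_config(seed = 22)
  g <- simulate_genome(cfg)
  v <- simulate_variants(cfg, g, "female")
  tr <- simulate_depth(cfg, g, "female")
  vcf_in <- tempfile(fileext = ".vcf")
  write_sim_vcf(v$records, scaffold_lengths(g$chromosome), vcf_in)
  out <- tempfile(fileext = ".vcf")
  bed <- tempfile(fileext = ".bed")
  res <- filter_vcf_file(vcf_in, tr, out, bed_path = bed)
  expect_equal(res$n_input, nrow(v$records))
  expect_gt(res$n_quality_dropped, 0)
  reread <- read_vcf(out)
  expect_equal(nrow(reread), nrow(res$records))
  expect_true(all(quality_filter(reread)))
  expect_gt(nrow(data.table::fread(bed)), 0)
})
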
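#' Read a single-sample VCF into a variant table
#'
#' Expects a VCF 4.x file with one sample whose FORMAT carries `DP`, `GQ`
#' and `SP` (strand-bias Phred score, as emitted by bcftools). Records with a
#' missing value in any required field (GT, DP, GQ, SP) are excluded with a
#' warning; the number of exclusions is available as `attr(x, "skipped")`.
#'
#' @param path VCF file (plain or bgzip)
#' @return data.table with one row per retained record: `scaffold`, `pos`
#'   (1-based), `ref`, `alt` (comma-joined), `n_alt`, `qual`, `dp`, `gq`,
#'   `sp`, `gt`
#' @export
read_vcf <- function(path) {
  flatten_vcf(VariantAnnotation::readVcf(path))
}

flatten_vcf <- function(vcf) {
  n <- nrow(vcf)
  rr <- SummarizedExperiment::rowRanges(vcf)
  g <- VariantAnnotation::geno(vcf)
  get_field <- function(name) {
    if (!name %in% names(g)) return(rep(NA_real_, n))
    v <- g[[name]][, 1L]
    if (is.list(v)) v <- vapply(v, function(x) if (length(x)) x[[1L]] else NA_real_, 0)
    as.numeric(v)
  }
  gt <- if ("GT" %in% names(g)) as.character(g$GT[, 1L]) else rep(NA_character_, n)
  gt[gt %in% c(".", "./.", ".|.")] <- NA_character_
  alt_list <- VariantAnnotation::alt(vcf)
  rec <- data.table(
    scaffold = as.character(seqnames(rr)),
    pos = start(rr),
    ref = as.character(VariantAnnotation::ref(vcf)),
    alt = vapply(as.list(alt_list), function(a) paste(as.character(a), collapse = ","), ""),
    n_alt = lengths(alt_list),
    qual = as.numeric(VariantAnnotation::qual(vcf)),
    dp = get_field("DP"), gq = get_field("GQ"), sp = get_field("SP"),
    gt = gt)
  bad <- is.na(rec$gt) | is.na(rec$dp) | is.na(rec$gq) | is.na(rec$sp)
  if (any(bad))
    warnf("%d record(s) missing a required FORMAT value (GT/DP/GQ/SP) were excluded",
          sum(bad))
  out <- rec[!bad]
  setattr(out, "skipped", sum(bad))
  out[]
}

#' Site-quality filter for variant records
#'
#' A record is dropped iff any of: `QUAL < 20`, `SP > 60`, `DP < 5`,
#' `GQ < 20` (boundaries themselves are kept). Thresholds are the bcftools
#' expression `QUAL < 20.0 || FORMAT/SP > 60.0 || FORMAT/DP < 5.0 ||
#' FORMAT/GQ < 20.0` commonly used for single-sample mammalian resequencing.
#'
#' @param records variant table from [read_vcf()]
#' @param min_qual,max_sp,min_dp,min_gq thresholds
#' @return logical keep vector, one element per record
#' @export
quality_filter <- function(records, min_qual = 20, max_sp = 60,
                           min_dp = 5, min_gq = 20) {
  with(records, !(qual < min_qual | sp > max_sp | dp < min_dp | gq < min_gq))
}

#' Coverage-band retention mask from a depth track
#'
#' Maximal runs of bases whose depth lies within
#' `[lower x median, upper x median]` (inclusive at both ends), per scaffold.
#' Defaults retain regions with 50-250% of the whole-genome median coverage.
#'
#' @param track a `depth_track`
#' @param lower,upper band bounds as fractions of the genome median
#' @param genome_median override for the genome-wide median depth
#' @return a `coverage_mask` data.table (`scaffold`, `start`, `end`; 0-based
#'   half-open intervals, sorted and non-overlapping)
#' @export
build_coverage_mask <- function(track, lower = 0.5, upper = 2.5,
                                genome_median = NULL) {
  stopifnot(inherits(track, "depth_track"))
  gm <- genome_median %||% track$genome_median
  if (gm <= 0) stopf("genome median depth must be positive (got %s)", gm)
  lo <- lower * gm; hi <- upper * gm
  rows <- lapply(names(track$rle), function(id) {
    r <- track$rle[[id]]
    inband <- r$values >= lo & r$values <= hi
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    iv <- data.table(start = starts[inband], end = ends[inband])
    if (!nrow(iv)) return(NULL)
    # merge runs that touch (adjacent in-band runs of different depth)
    grp <- cumsum(c(1L, as.integer(iv$start[-1L] != iv$end[-nrow(iv)])))
    iv <- iv[, .(start = start[1L], end = end[.N]), by = grp][, grp := NULL]
    cbind(data.table(scaffold = id), iv)
  })
  out <- rbindlist(rows)
  setattr(out, "class", c("coverage_mask", class(out)))
  out
}

#' Keep variant records inside a coverage mask
#'
#' A record is retained when `pos - 1` (0-based) falls inside one of the
#' mask's half-open intervals for its scaffold; records on scaffolds absent
#' from the mask are dropped. The number of dropped records is available as
#' `attr(x, "dropped")`.
#'
#' @param records variant table
#' @param mask a `coverage_mask`
#' @return the retained records
#' @export
apply_mask <- function(records, mask) {
  keep <- logical(nrow(records))
  for (id in unique(records$scaffold)) {
    ri <- which(records$scaffold == id)
    iv <- mask[scaffold == id]
    if (!nrow(iv)) next
    p0 <- records$pos[ri] - 1
    hit <- findInterval(p0, iv$start) # interval index whose start <= p0
    ok <- hit >= 1L & p0 < iv$end[pmax(hit, 1L)]
    keep[ri] <- ok
  }
  out <- records[keep]
  setattr(out, "dropped", sum(!keep))
  out[]
}

#' Split variant records into SNPs and indels
#'
#' A record is a SNP iff the REF allele and every ALT allele have length 1;
#' mixed multi-allelic records go to the indel bucket. Downstream
#' heterozygosity analyses use SNPs only.
#'
#' @param records variant table
#' @return list with elements `snps` and `indels`
#' @export
split_snp_indel <- function(records) {
  is_snp <- nchar(records$ref) == 1L &
    vapply(strsplit(records$alt, ",", fixed = TRUE),
           function(a) all(nchar(a) == 1L), TRUE)
  list(snps = records[is_snp], indels = records[!is_snp])
}

#' Heterozygous genotype test
#'
#' TRUE when the genotype carries two distinct allele indices (0/1, 1/2,
#' 0|1, ...); homozygous-alternative genotypes are not heterozygous.
#'
#' @param gt character vector of VCF GT strings
#' @return logical vector
#' @export
is_het <- function(gt) {
  vapply(strsplit(gt, "[/|]"), function(a) {
    a <- a[a != "."]
    length(unique(a)) > 1L
  }, TRUE)
}

#' Filter a VCF file by site quality and coverage band
#'
#' Reads the VCF, applies [quality_filter()] then [apply_mask()] built from
#' `track`, and writes the retained records to `out_path` together with a BED
#' of the retained-coverage intervals.
#'
#' @param vcf_path input VCF
#' @param track a `depth_track` for the same sample
#' @param out_path filtered VCF path
#' @param bed_path optional path for the coverage-mask BED
#' @param ... passed to [quality_filter()]
#' @return (invisibly) list with the retained record table, the mask, and
#'   drop counts per stage
#' @export
filter_vcf_file <- function(vcf_path, track, out_path, bed_path = NULL, ...) {
  vcf <- VariantAnnotation::readVcf(vcf_path)
  rec <- suppressWarnings(flatten_vcf(vcf))
  keep_q <- quality_filter(rec, ...)
  mask <- build_coverage_mask(track)
  kept <- apply_mask(rec[keep_q], mask)
  rr <- SummarizedExperiment::rowRanges(vcf)
  idx <- match(paste(kept$scaffold, kept$pos),
               paste(as.character(seqnames(rr)), start(rr)))
  VariantAnnotation::writeVcf(vcf[idx], out_path)
  if (!is.null(bed_path))
    fwrite(mask[, .(scaffold, start, end)], bed_path, sep = "\t",
           col.names = FALSE)
  invisible(list(records = kept, mask = mask,
                 n_input = nrow(rec),
                 n_quality_dropped = sum(!keep_q),
                 n_coverage_dropped = attr(kept, "dropped")))
}
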
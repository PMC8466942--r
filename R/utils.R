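#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Median of a multiset given as value/count pairs
#'
#' Equivalent to `stats::median(rep(values, counts))` without expanding the
#' multiset; for an even total the two middle order statistics are averaged.
#'
#' @param values numeric vector of distinct values (need not be sorted)
#' @param counts non-negative counts, same length as `values`
#' @return the median as a numeric scalar
#' @export
weighted_median_counts <- function(values, counts) {
  stopifnot(length(values) == length(counts), all(counts >= 0))
  keep <- counts > 0
  values <- values[keep]; counts <- counts[keep]
  if (!length(values)) return(NA_real_)
  o <- order(values)
  values <- values[o]; counts <- counts[o]
  n <- sum(counts)
  cs <- cumsum(counts)
  lo <- values[which(cs >= (n + 1) %/% 2)[1L]]
  hi <- values[which(cs >= n %/% 2 + 1L)[1L]]
  if (n %% 2 == 1L) lo else (lo + hi) / 2
}

# maximal runs of TRUE in a logical vector, as 0-based half-open intervals
runs_true <- function(x) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values
  data.table(start = starts[keep], end = ends[keep])
}

# IUPAC nucleotide expansion sets (primer side)
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

is_iupac <- function(s) {
  all(strsplit(toupper(s), "")[[1]] %in% names(IUPAC_SETS))
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# substitute k positions of a primer with a different base (seeded by caller)
mutate_seq <- function(s, k) {
  ch <- strsplit(s, "")[[1]]
  idx <- sample(length(ch), k)
  for (i in idx) {
    ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1L)
  }
  paste(ch, collapse = "")
}

revcomp_chr <- function(s) {
  as.character(reverseComplement(DNAString(s)))
}
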
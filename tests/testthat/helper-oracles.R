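# Independent oracles and tiny fixture builders shared across tests.
# Oracles deliberately use a different algorithmic route than the package.

# N50 by explicit walk over the descending-sorted lengths
n50_oracle <- function(lengths) {
  s <- sort(lengths, decreasing = TRUE)
  half <- sum(s) / 2
  acc <- 0
  for (l in s) {
    acc <- acc + l
    if (acc >= half) return(l)
  }
}

# brute-force Hamming scan of a primer over every position of both strands;
# IUPAC handled on the primer side only, genome N never matches
IUPAC_ORACLE <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

revcomp_oracle <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N",
            R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
            B = "V", V = "B", D = "H", H = "D")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

hamming_sites_oracle <- function(seqs, primer, max_mm = 4) {
  out <- list()
  scan <- function(id, seq_chr, pat, strand) {
    p <- strsplit(pat, "")[[1]]
    s <- strsplit(seq_chr, "")[[1]]
    k <- length(p)
    sets <- IUPAC_ORACLE[p]
    for (i in seq_len(length(s) - k + 1L)) {
      mm <- 0L
      for (j in seq_len(k)) {
        base <- s[i + j - 1L]
        if (base == "N" || !(base %in% sets[[j]])) mm <- mm + 1L
        if (mm > max_mm) break
      }
      if (mm <= max_mm)
        out[[length(out) + 1L]] <<- data.frame(
          scaffold = id, start = i - 1L, end = i + k - 1L,
          strand = strand, mismatches = mm)
    }
  }
  for (id in names(seqs)) {
    scan(id, seqs[[id]], toupper(primer), "+")
    scan(id, seqs[[id]], revcomp_oracle(toupper(primer)), "-")
  }
  if (!length(out))
    return(data.frame(scaffold = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      mismatches = integer(0)))
  df <- do.call(rbind, out)
  df[order(df$scaffold, df$start, df$strand), ]
}

# one-sided Mann-Whitney p by pairwise-comparison U over all value subsets
mw_oracle_p <- function(a, b) {
  u_of <- function(x, y) {
    u <- 0
    for (xi in x) for (yi in y) u <- u + (xi > yi) + 0.5 * (xi == yi)
    u
  }
  pooled <- c(a, b)
  n1 <- length(a)
  u_obs <- u_of(a, b)
  idx <- utils::combn(length(pooled), n1)
  hits <- 0
  for (k in seq_len(ncol(idx))) {
    aa <- pooled[idx[, k]]
    bb <- pooled[-idx[, k]]
    if (u_of(aa, bb) >= u_obs - 1e-9) hits <- hits + 1
  }
  hits / ncol(idx)
}

window_median_oracle <- function(d, ws) {
  nw <- ceiling(length(d) / ws)
  vapply(seq_len(nw), function(i) {
    stats::median(d[((i - 1) * ws + 1):min(i * ws, length(d))])
  }, 0)
}

random_assembly <- function(n_scaffolds, max_len = 50) {
  lens <- sample.int(max_len, n_scaffolds, replace = TRUE)
  seqs <- vapply(lens, function(l)
    paste(sample(c("A", "C", "G", "T", "N"), l, replace = TRUE,
                 prob = c(0.24, 0.24, 0.24, 0.24, 0.04)), collapse = ""), "")
  names(seqs) <- paste0("s", seq_len(n_scaffolds))
  genome_assembly(seqs)
}

write_tmp_fasta <- function(records, path = tempfile(fileext = ".fa")) {
  writeLines(unlist(lapply(names(records), function(id)
    c(paste0(">", id), records[[id]]))), path)
  path
}

# small config used across tests (fast; ~1.3 Mbp genome)
test_config <- function(seed = 11, n_autosomes = 2L, autosome_length = 4e5,
                        x_length = 3e5, par_length = 1e5,
                        draft_fragmentation = 5e4, ...) {
  sim_config(seed = seed, n_autosomes = n_autosomes,
             autosome_length = autosome_length, x_length = x_length,
             par_length = par_length,
             draft_fragmentation = draft_fragmentation, ...)
}
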
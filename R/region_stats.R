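#' Split a 100-kbp window track into the five standard subsets
#'
#' Subsets: `all` (every window), `noX` (autosomes), `onlyX` (X scaffold),
#' `noPAR` (X windows outside the PAR) and `PAR`. A window belongs to `PAR`
#' only when its full span lies within a PAR interval; boundary-straddling
#' windows go to `noPAR` so the small PAR sample is not diluted with mixed
#' windows. The identities `all = noX + onlyX` and `onlyX = noPAR + PAR`
#' hold exactly.
#'
#' @param track a `window_track` (heterozygous SNPs/kbp)
#' @param x_scaffold X scaffold id
#' @param par a `par_call` (or NULL for no PAR)
#' @return named list of five numeric vectors of window densities
#' @export
subset_windows <- function(track, x_scaffold, par = NULL) {
  if (!is.null(par)) {
    if (!identical(par$x_scaffold, x_scaffold))
      stopf("PAR call is on scaffold '%s', not on the X scaffold '%s'",
            par$x_scaffold, x_scaffold)
  }
  on_x <- track$scaffold == x_scaffold
  in_par <- rep(FALSE, nrow(track))
  if (!is.null(par) && nrow(par$intervals)) {
    for (i in seq_len(nrow(par$intervals))) {
      in_par <- in_par | (on_x & track$start >= par$intervals$start[i] &
                            track$end <= par$intervals$end[i])
    }
  }
  list(all = track$value,
       noX = track$value[!on_x],
       onlyX = track$value[on_x],
       noPAR = track$value[on_x & !in_par],
       PAR = track$value[in_par])
}

mw_u <- function(a, b) {
  r <- rank(c(a, b))
  sum(r[seq_along(a)]) - length(a) * (length(a) + 1) / 2
}

# exact one-sided p by enumeration of all C(n1+n2, n1) rank assignments
mw_exact_p <- function(a, b) {
  n1 <- length(a); n <- n1 + length(b)
  r <- rank(c(a, b))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  cmb <- combn(n, n1)
  u_all <- colSums(matrix(r[cmb], nrow = n1)) - n1 * (n1 + 1) / 2
  mean(u_all >= u_obs - 1e-9)
}

#' One-sided Mann-Whitney rank-sum test
#'
#' Tests the alternative that sample `a` is stochastically greater than
#' sample `b`. Small samples (`min(n1, n2) <= 8` and `n1 + n2 <= 25` by
#' default) use exact enumeration over all rank assignments (valid under
#' ties); larger samples use the tie-corrected normal approximation with
#' continuity correction. When every value in both samples is identical the
#' test is degenerate and `p = 1` is returned with a warning.
#'
#' @param a,b numeric samples
#' @param alternative only `"a_greater"` is offered; swap the arguments for
#'   the opposite direction
#' @param exact force (`TRUE`/`FALSE`) or auto-select (`NULL`) the exact route
#' @return list: `U` (statistic for `a`), `raw_p`, `n1`, `n2`, `method`
#' @export
mann_whitney_one_sided <- function(a, b, alternative = "a_greater",
                                   exact = NULL) {
  stopifnot(alternative == "a_greater", length(a) >= 1, length(b) >= 1)
  n1 <- length(a); n2 <- length(b); n <- n1 + n2
  u <- mw_u(a, b)
  if (length(unique(c(a, b))) == 1L) {
    warnf("all values identical in both samples; test is degenerate")
    return(list(U = u, raw_p = 1, n1 = n1, n2 = n2, method = "degenerate"))
  }
  use_exact <- exact %||% (min(n1, n2) <= 8 && n <= 25)
  if (use_exact) {
    p <- mw_exact_p(a, b)
    method <- "exact"
  } else {
    r <- rank(c(a, b))
    ties <- table(r)
    mu <- n1 * n2 / 2
    sig2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sig2 <= 0) {
      warnf("zero rank variance; test is degenerate")
      return(list(U = u, raw_p = 1, n1 = n1, n2 = n2, method = "degenerate"))
    }
    z <- (u - mu - 0.5) / sqrt(sig2)
    p <- pnorm(z, lower.tail = FALSE)
    method <- "normal"
  }
  list(U = u, raw_p = p, n1 = n1, n2 = n2, method = method)
}

#' Run the standard PAR/autosome heterozygosity comparisons
#'
#' For every individual with a non-empty PAR subset, tests "PAR is more
#' heterozygous than autosomes" (PAR vs noX); for females additionally
#' "autosomes are more heterozygous than the hemizygous X" (noX vs noPAR).
#' Both are one-sided Mann-Whitney tests; p-values are Bonferroni-adjusted
#' with the family size equal to the number of tests actually run in this
#' invocation.
#'
#' @param subsets_by_individual named list; each element the output of
#'   [subset_windows()] for one individual
#' @param sexes named character vector (`"male"`/`"female"`) per individual
#' @param alpha significance level applied after adjustment
#' @return data.table with one row per test: individual, comparison,
#'   alternative, U, raw_p, adjusted_p, n1, n2, significant
#' @export
run_region_comparisons <- function(subsets_by_individual, sexes, alpha = 0.01) {
  rows <- list()
  for (id in names(subsets_by_individual)) {
    s <- subsets_by_individual[[id]]
    if (!length(s$PAR)) {
      message(sprintf("no PAR windows for '%s'; PAR comparison skipped", id))
    } else {
      t1 <- mann_whitney_one_sided(s$PAR, s$noX)
      rows[[paste0(id, ".par")]] <- data.table(
        individual = id, comparison = "PAR_vs_autosomes",
        alternative = "PAR more heterozygous than autosomes",
        U = t1$U, raw_p = t1$raw_p, n1 = t1$n1, n2 = t1$n2)
    }
    if (identical(unname(sexes[id]), "female") && length(s$noPAR)) {
      t2 <- mann_whitney_one_sided(s$noX, s$noPAR)
      rows[[paste0(id, ".nopar")]] <- data.table(
        individual = id, comparison = "autosomes_vs_noPAR",
        alternative = "autosomes more heterozygous than hemizygous X",
        U = t2$U, raw_p = t2$raw_p, n1 = t2$n1, n2 = t2$n2)
    }
  }
  out <- rbindlist(rows)
  if (!nrow(out)) return(out)
  out[, adjusted_p := pmin(1, raw_p * .N)]
  out[, significant := adjusted_p < alpha]
  out[]
}
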
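#' Identify the X chromosome from a male coverage-band profile
#'
#' In a male sample the X outside the pseudoautosomal region is hemizygous
#' and sequenced at roughly half the autosomal depth, so among the
#' chromosome-sized scaffolds the X is the one dominated by half-band
#' windows. Female data cannot identify the X by depth (the X is then
#' indistinguishable from an autosome) and is rejected.
#'
#' @param profile a `coverage_profile` (typically 1 Mbp windows)
#' @param sex `"male"` or `"female"`
#' @param min_half_fraction minimum fraction of half-band windows required
#' @param size_fraction scaffolds at least this fraction of the longest
#'   scaffold's length count as chromosome-sized (C-scaffold-sized)
#' @return the X scaffold id
#' @export
identify_x <- function(profile, sex = c("male", "female"),
                       min_half_fraction = 0.5, size_fraction = 0.1) {
  sex <- match.arg(sex)
  if (sex == "female")
    stopf("X cannot be identified from depth in a female sample; %s",
          "use whole-genome alignment to a related karyotyped species (unsupported here)")
  sizes <- profile[, .(len = max(end)), by = scaffold]
  big <- sizes[len >= size_fraction * max(len), scaffold]
  frac <- profile[scaffold %in% big,
                  .(half_frac = mean(band == "half")), by = scaffold]
  best <- frac[which.max(half_frac)]
  if (best$half_frac <= min_half_fraction)
    stopf("X not identifiable: no chromosome-sized scaffold has > %.0f%% half-coverage windows (best %.0f%%)",
          100 * min_half_fraction, 100 * best$half_frac)
  best$scaffold
}

#' An (possibly empty) PAR call
#' @param x_scaffold X scaffold id
#' @param intervals data.table with `start`, `end` (0-based half-open)
#' @return a `par_call` list with `x_scaffold`, `intervals`, `par_length`
#' @export
par_call <- function(x_scaffold, intervals = data.table(start = numeric(0),
                                                        end = numeric(0))) {
  setDT(intervals)
  structure(list(x_scaffold = x_scaffold, intervals = intervals,
                 par_length = sum(intervals$end - intervals$start)),
            class = "par_call")
}

#' @export
print.par_call <- function(x, ...) {
  cat(sprintf("<par_call> X = %s, %d region(s), %s bp\n", x$x_scaffold,
              nrow(x$intervals), format(x$par_length, big.mark = ",")))
  invisible(x)
}

#' Core PAR detector on a window-median profile of the X scaffold
#'
#' Three stages: (1) windows whose median depth is at least
#' `threshold` x genome median are marked and adjacent marked windows merged
#' into runs; (2) only merged runs spanning at least `min_run` bases are
#' retained; (3) two retained runs are bridged into one region when the
#' pooled median of the intervening windows' medians is itself at least
#' `threshold` x genome median (bridging is applied left to right and can
#' chain).
#'
#' @param medians per-window median depths along the X scaffold, in order
#' @param starts,ends window coordinates (0-based half-open)
#' @param genome_median whole-genome median depth
#' @param x_scaffold scaffold id recorded in the call
#' @param threshold fraction of the genome median a window must reach
#' @param min_run minimum retained run length in bases
#' @return a `par_call`
#' @export
detect_par_core <- function(medians, starts, ends, genome_median, x_scaffold,
                            threshold = 0.7, min_run = 1e5) {
  stopifnot(length(medians) == length(starts), length(starts) == length(ends),
            genome_median > 0)
  cut <- threshold * genome_median
  marked <- medians >= cut
  runs <- runs_true(marked)                       # in window indices
  if (!nrow(runs)) {
    warnf("no windows reach %.0f%% of genome median on %s", 100 * threshold,
          x_scaffold)
    return(par_call(x_scaffold))
  }
  reg <- data.table(start = starts[runs$start + 1L], end = ends[runs$end],
                    wstart = runs$start, wend = runs$end)
  reg <- reg[end - start >= min_run]
  if (!nrow(reg)) {
    warnf("no merged run of >= %d bp on %s", as.integer(min_run), x_scaffold)
    return(par_call(x_scaffold))
  }
  # stage 3: bridge across gaps whose pooled window median stays high enough
  merged <- reg[1L]
  if (nrow(reg) > 1L) {
    for (i in 2L:nrow(reg)) {
      gap_idx <- seq.int(merged$wend[nrow(merged)] + 1L, reg$wstart[i])
      pooled <- stats::median(medians[gap_idx])
      if (length(gap_idx) && pooled >= cut) {
        merged[nrow(merged), `:=`(end = reg$end[i], wend = reg$wend[i])]
      } else {
        merged <- rbind(merged, reg[i])
      }
    }
  }
  par_call(x_scaffold, merged[, .(start, end)])
}

#' Detect the pseudoautosomal region on an identified X scaffold
#'
#' Computes median depth in stacking windows (10 kbp by default) along the X
#' scaffold and applies the three-stage merge in [detect_par_core()], using
#' the whole-genome median stored in the track.
#'
#' @param track a `depth_track` from a male sample
#' @param x_scaffold scaffold id of the X chromosome
#' @param window_size refinement window width (bases)
#' @param threshold,min_run see [detect_par_core()]
#' @return a `par_call`
#' @export
detect_par <- function(track, x_scaffold, window_size = 1e4,
                       threshold = 0.7, min_run = 1e5) {
  stopifnot(inherits(track, "depth_track"))
  if (!x_scaffold %in% names(track$rle))
    stopf("scaffold '%s' not in depth track", x_scaffold)
  prof <- window_median_depth(track, window_size, scaffolds = x_scaffold)
  detect_par_core(prof$median_depth, prof$start, prof$end,
                  track$genome_median, x_scaffold,
                  threshold = threshold, min_run = min_run)
}

#' Write PAR intervals as BED
#' @param par a `par_call`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_par_bed <- function(par, path) {
  bed <- data.table(scaffold = par$x_scaffold,
                    start = par$intervals$start, end = par$intervals$end,
                    name = "PAR")
  fwrite(bed, path, sep = "\t", col.names = FALSE)
  invisible(path)
}
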
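#' Build a read-depth track
#'
#' Per-base depth is stored run-length encoded, one run set per scaffold, so
#' a full per-base vector is only ever materialized for one scaffold at a
#' time. The whole-genome median depth is computed over the concatenation of
#' all scaffolds (X included) at construction time.
#'
#' @param depths named list; each element is an integer vector of per-base
#'   depths or a base [rle] object
#' @return a `depth_track`: run-length data, scaffold lengths, `genome_median`
#' @export
depth_track <- function(depths) {
  stopifnot(is.list(depths), !is.null(names(depths)), all(names(depths) != ""))
  rles <- lapply(depths, function(d) if (inherits(d, "rle")) d else rle(as.numeric(d)))
  for (r in rles) if (any(r$values < 0)) stopf("negative depth")
  lens <- vapply(rles, function(r) sum(r$lengths), 0)
  vals <- unlist(lapply(rles, `[[`, "values"), use.names = FALSE)
  cnts <- unlist(lapply(rles, `[[`, "lengths"), use.names = FALSE)
  agg <- rowsum(cnts, group = vals)
  gm <- weighted_median_counts(as.numeric(rownames(agg)), agg[, 1L])
  structure(list(rle = rles, lengths = setNames(lens, names(rles)),
                 genome_median = gm),
            class = "depth_track")
}

#' @export
print.depth_track <- function(x, ...) {
  cat(sprintf("<depth_track> %d scaffolds, %s bases, genome median depth %.1f\n",
              length(x$rle), format(sum(x$lengths), big.mark = ","),
              x$genome_median))
  invisible(x)
}

#' Per-base depth of one scaffold
#' @param track a `depth_track`
#' @param id scaffold id
#' @return numeric vector of per-base depths
#' @export
scaffold_depth <- function(track, id) {
  if (!id %in% names(track$rle)) stopf("scaffold '%s' not in depth track", id)
  inverse.rle(track$rle[[id]])
}

#' Read a bedGraph depth file into a depth track
#'
#' Expects contiguous coverage intervals per scaffold (as produced by
#' `bedtools genomecov -bga`); positions not covered by any interval are
#' taken as depth 0, using `scaffold_lengths` to pad scaffold ends when
#' given.
#'
#' @param path bedGraph file (plain or gzipped)
#' @param scaffold_lengths optional named vector of true scaffold lengths
#' @return a `depth_track`
#' @export
read_bedgraph <- function(path, scaffold_lengths = NULL) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  dt <- data.table(scaffold = as.character(seqnames(gr)),
                   start = start(gr) - 1L, end = end(gr),
                   depth = as.numeric(gr$score))
  setorder(dt, scaffold, start)
  rles <- lapply(split(dt, by = "scaffold", sorted = TRUE), function(d) {
    # interleave zero-depth runs for any uncovered gaps
    gap <- d$start - c(0, d$end[-nrow(d)])
    if (any(gap < 0)) stopf("overlapping bedGraph intervals on %s",
                            d$scaffold[1L])
    lens <- as.vector(rbind(gap, d$end - d$start))
    vals <- as.vector(rbind(0, d$depth))
    target <- scaffold_lengths[[d$scaffold[1L]]]
    cursor <- d$end[nrow(d)]
    if (!is.null(target) && target > cursor) {
      lens <- c(lens, target - cursor); vals <- c(vals, 0)
    }
    keep <- lens > 0
    structure(list(lengths = lens[keep], values = vals[keep]), class = "rle")
  })
  depth_track(rles)
}

#' Write a depth track as bedGraph
#' @param track a `depth_track`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_bedgraph <- function(track, path) {
  rows <- lapply(names(track$rle), function(id) {
    r <- track$rle[[id]]
    ends <- cumsum(r$lengths)
    data.table(scaffold = id, start = ends - r$lengths, end = ends,
               depth = r$values)
  })
  fwrite(rbindlist(rows), path, sep = "\t", col.names = FALSE)
  invisible(path)
}

band_of <- function(ratio) {
  # Half and full coverage bands; the 0.75 boundary belongs to "full".
  ifelse(ratio >= 0.25 & ratio < 0.75, "half",
         ifelse(ratio >= 0.75 & ratio <= 1.25, "full", "other"))
}

window_median_one <- function(d, window_size) {
  len <- length(d)
  nw <- ceiling(len / window_size)
  starts <- (seq_len(nw) - 1L) * window_size
  ends <- pmin(starts + window_size, len)
  med <- vapply(seq_len(nw),
                function(i) stats::median(d[(starts[i] + 1L):ends[i]]), 0)
  list(start = starts, end = ends, median = med)
}

#' Median depth in stacking windows, with coverage-band labels
#'
#' Windows are adjacent, non-overlapping, and anchored at the scaffold start;
#' a trailing partial window uses its actual bases. Each window is labelled
#' by the ratio of its median depth to the whole-genome median: `half` for
#' ratios in \[0.25, 0.75), `full` for \[0.75, 1.25\], `other` outside.
#'
#' @param track a `depth_track`
#' @param window_size window width in bases (10 kbp for PAR refinement,
#'   1 Mbp for the chromosome scan)
#' @param scaffolds optional subset of scaffold ids
#' @return a `coverage_profile` data.table with columns `scaffold`, `start`,
#'   `end`, `median_depth`, `ratio`, `band`; attributes `window_size` and
#'   `genome_median`
#' @export
window_median_depth <- function(track, window_size, scaffolds = NULL) {
  stopifnot(inherits(track, "depth_track"), window_size >= 1)
  ids <- scaffolds %||% names(track$rle)
  missing <- setdiff(ids, names(track$rle))
  if (length(missing)) stopf("scaffold '%s' not in depth track", missing[1L])
  rows <- list()
  for (id in ids) {
    if (track$lengths[[id]] == 0) { warnf("empty scaffold '%s' skipped", id); next }
    w <- window_median_one(scaffold_depth(track, id), window_size)
    rows[[id]] <- data.table(scaffold = id, start = w$start, end = w$end,
                             median_depth = w$median)
  }
  prof <- rbindlist(rows)
  prof[, ratio := median_depth / track$genome_median]
  prof[, band := band_of(ratio)]
  coverage_profile(prof, window_size, track$genome_median)
}

coverage_profile <- function(dt, window_size, genome_median) {
  setattr(dt, "window_size", window_size)
  setattr(dt, "genome_median", genome_median)
  setattr(dt, "class", c("coverage_profile", class(dt)))
  dt
}
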
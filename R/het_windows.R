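#' Number of complete stacking windows per scaffold
#'
#' Windows are non-overlapping, anchored at the scaffold start, and never
#' span scaffolds; trailing partial windows are discarded (not rescaled).
#'
#' @param lengths scaffold lengths in bases
#' @param window_size window width in bases
#' @return total count of complete windows
#' @export
window_count <- function(lengths, window_size) {
  stopifnot(window_size >= 1)
  sum(floor(lengths / window_size))
}

#' Heterozygous-SNP density in stacking windows
#'
#' Counts heterozygous SNPs in non-overlapping windows (typically 100 kbp
#' and 1 Mbp) and scales to SNPs per kbp. A SNP with 1-based position `pos`
#' falls in the window whose half-open span contains `pos - 1`. Gap (N)
#' content is not subtracted from the window span; densities are per nominal
#' window size.
#'
#' @param snps data.frame/data.table of heterozygous SNPs with columns
#'   `scaffold` and `pos` (1-based)
#' @param lengths named vector of scaffold lengths, or a `genome_assembly`
#' @param window_size window width in bases (>= 1 kbp)
#' @return a `window_track` data.table: `scaffold`, `start`, `end`,
#'   `n_snps`, `value` (SNPs/kbp); attribute `window_size`
#' @export
het_density <- function(snps, lengths, window_size) {
  stopifnot(window_size >= 1000)
  if (inherits(lengths, "genome_assembly")) lengths <- scaffold_lengths(lengths)
  snps <- as.data.table(snps)
  if (nrow(snps)) {
    missing <- setdiff(unique(snps$scaffold), names(lengths))
    if (length(missing))
      stopf("SNP on scaffold '%s' absent from assembly", missing[1L])
    if (any(snps$pos < 1) ||
        any(snps$pos > lengths[snps$scaffold]))
      stopf("SNP position outside scaffold bounds")
  }
  rows <- lapply(names(lengths), function(id) {
    nw <- floor(lengths[[id]] / window_size)
    if (nw == 0L) return(NULL)
    starts <- (seq_len(nw) - 1) * window_size
    p0 <- snps[scaffold == id, pos] - 1
    widx <- p0 %/% window_size + 1              # 1-based window index
    counts <- tabulate(widx[widx <= nw], nbins = nw)
    data.table(scaffold = id, start = starts, end = starts + window_size,
               n_snps = counts, value = counts / (window_size / 1000))
  })
  out <- rbindlist(rows)
  if (!nrow(out))
    out <- data.table(scaffold = character(0), start = numeric(0),
                      end = numeric(0), n_snps = integer(0),
                      value = numeric(0))
  setattr(out, "window_size", window_size)
  setattr(out, "class", c("window_track", class(out)))
  out
}

#' Summarize a window track
#'
#' Median and mean SNPs/kbp over the pooled windows of all scaffolds, plus
#' window and SNP counts (SNPs falling in complete windows only). With zero
#' windows (every scaffold shorter than the window) statistics are `NA` and
#' a warning is raised -- the situation that makes 1-Mbp landscapes
#' uninformative on fragmented draft assemblies.
#'
#' @param track a `window_track`
#' @return list: `n_windows`, `median`, `mean`, `total_het_snps`
#' @export
summarize_track <- function(track) {
  if (!nrow(track)) {
    warnf("track has zero complete windows")
    return(list(n_windows = 0L, median = NA_real_, mean = NA_real_,
                total_het_snps = 0L))
  }
  list(n_windows = nrow(track),
       median = stats::median(track$value),
       mean = mean(track$value),
       total_het_snps = sum(track$n_snps))
}

#' Write a window track and its summary as TSVs
#' @param track a `window_track`
#' @param path output TSV path (BED-like: scaffold, start, end, snps_per_kbp)
#' @return the summary, invisibly; also writes `<path>.summary.tsv`
#' @export
write_window_track <- function(track, path) {
  fwrite(track[, .(scaffold, start, end, snps_per_kbp = value)], path,
         sep = "\t")
  s <- summarize_track(track)
  fwrite(data.table(n_windows = s$n_windows, median = s$median,
                    mean = s$mean, total_het_snps = s$total_het_snps),
         paste0(tools::file_path_sans_ext(path), ".summary.tsv"), sep = "\t")
  invisible(s)
}
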
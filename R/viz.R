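#' Assign values to color bins
#'
#' Bins are left-closed: a value equal to a threshold lands in the upper
#' bin. Default thresholds 0.1 and 0.75 SNPs/kbp separate "very low",
#' "low-intermediate" and "high" heterozygosity.
#'
#' @param values numeric vector
#' @param breaks strictly increasing thresholds
#' @return integer bin index in `1..length(breaks)+1`
#' @export
assign_bins <- function(values, breaks = c(0.1, 0.75)) {
  if (is.unsorted(breaks, strictly = TRUE))
    stopf("thresholds must be strictly increasing")
  findInterval(values, breaks) + 1L
}

open_device <- function(file, format = c("png", "svg"), width = 9,
                        height = 6) {
  format <- match.arg(format)
  if (format == "png") {
    grDevices::png(file, width = width, height = height, units = "in",
                   res = 120)
  } else {
    grDevices::svg(file, width = width, height = height)
  }
}

chrom_bar_canvas <- function(lens, title_txt) {
  n <- length(lens)
  plot.new()
  plot.window(xlim = c(0, max(lens)), ylim = c(0.5, n + 0.5))
  axis(1, at = pretty(c(0, max(lens))),
       labels = pretty(c(0, max(lens))) / 1e6)
  mtext("position (Mbp)", side = 1, line = 2.2, cex = 0.8)
  axis(2, at = n:1, labels = names(lens), las = 2, cex.axis = 0.7)
  title(main = title_txt)
  setNames(n:1, names(lens))
}

#' Heatmap of windowed heterozygosity along chromosomes
#'
#' One horizontal bar per C-scaffold (ordered by length, longest on top);
#' each window is a colored cell by density bin.
#'
#' @param track a `window_track`
#' @param file output image path
#' @param breaks density thresholds (SNPs/kbp), see [assign_bins()]
#' @param colors one color per bin (`length(breaks) + 1`)
#' @param n_chromosomes optionally restrict to the longest n scaffolds
#' @param format `"png"` or `"svg"`
#' @return (invisibly) the per-window bin assignment table
#' @export
plot_het_heatmap <- function(track, file, breaks = c(0.1, 0.75),
                             colors = c("#08306B", "#4292C6", "#FEC44F"),
                             n_chromosomes = NULL, format = "png") {
  if (!nrow(track)) stopf("empty window track; nothing to plot")
  stopifnot(length(colors) == length(breaks) + 1L)
  lens <- track[, .(len = max(end)), by = scaffold]
  setorder(lens, -len)
  if (!is.null(n_chromosomes)) lens <- lens[seq_len(n_chromosomes)]
  d <- track[scaffold %in% lens$scaffold]
  d[, bin := assign_bins(value, breaks)]
  open_device(file, format)
  on.exit(dev.off())
  ypos <- chrom_bar_canvas(setNames(lens$len, lens$scaffold),
                           "Heterozygous SNP density")
  for (id in lens$scaffold) {
    w <- d[scaffold == id]
    y <- ypos[[id]]
    rect(w$start, y - 0.35, w$end, y + 0.35, col = colors[w$bin],
         border = NA)
  }
  legend("bottomright",
         legend = c(sprintf("< %.2g", breaks[1]),
                    if (length(breaks) > 1)
                      sprintf("[%.2g, %.2g)", head(breaks, -1), tail(breaks, -1)),
                    sprintf(">= %.2g", tail(breaks, 1))),
         fill = colors, cex = 0.7, title = "SNPs/kbp")
  invisible(d[, .(scaffold, start, end, value, bin)])
}

#' Boxplots of the five window subsets
#'
#' @param subsets output of [subset_windows()]
#' @param file output image path
#' @param clip drop values above this threshold from display (outlier
#'   clipping; NULL keeps everything)
#' @param format `"png"` or `"svg"`
#' @return `file`, invisibly
#' @export
plot_summary_boxplot <- function(subsets, file, clip = NULL, format = "png") {
  if (!length(subsets$all)) stopf("empty window subsets; nothing to plot")
  shown <- subsets
  if (!is.null(clip)) shown <- lapply(shown, function(v) v[v <= clip])
  open_device(file, format, width = 6, height = 5)
  on.exit(dev.off())
  boxplot(shown, ylab = "het SNPs / kbp", col = "#9ECAE1",
          main = "Window heterozygosity by region")
  invisible(file)
}

#' Coverage-band track along chromosomes
#'
#' Windows are colored by coverage band: dark blue for half coverage
#' (0.25-0.75x of the genome median), teal for full (0.75-1.25x), grey
#' otherwise; in a male sample the X body shows as half coverage and the
#' PAR stands out at full coverage.
#'
#' @param profile a `coverage_profile`
#' @param file output image path
#' @param format `"png"` or `"svg"`
#' @return `file`, invisibly
#' @export
plot_coverage_track <- function(profile, file, format = "png") {
  if (!nrow(profile)) stopf("empty coverage profile; nothing to plot")
  cols <- c(half = "#08306B", full = "#35978F", other = "#BDBDBD")
  lens <- profile[, .(len = max(end)), by = scaffold]
  setorder(lens, -len)
  open_device(file, format)
  on.exit(dev.off())
  ypos <- chrom_bar_canvas(setNames(lens$len, lens$scaffold),
                           "Depth of coverage bands")
  for (id in lens$scaffold) {
    w <- profile[scaffold == id]
    y <- ypos[[id]]
    rect(w$start, y - 0.35, w$end, y + 0.35, col = cols[w$band], border = NA)
  }
  legend("bottomright", legend = c("0.25-0.75x", "0.75-1.25x", "other"),
         fill = cols, cex = 0.7, title = "coverage")
  invisible(file)
}

#' Marker localization map (ideogram)
#'
#' C-scaffold bars with localized markers as colored dots (colored by
#' marker source); C-scaffolds without any marker are drawn light grey.
#'
#' @param markers per-marker table from [marker_table()], with an optional
#'   `source` column
#' @param lengths named scaffold lengths (C-scaffolds will be the longest
#'   `n_chromosomes`)
#' @param n_chromosomes number of C-scaffolds to draw
#' @param file output image path
#' @param format `"png"` or `"svg"`
#' @return (invisibly) list with `path` and the `labeled`/`unlabeled`
#'   C-scaffold ids
#' @export
plot_marker_map <- function(markers, lengths, n_chromosomes, file,
                            format = "png") {
  if (!nrow(markers)) stopf("empty marker table; nothing to plot")
  lens <- sort(lengths, decreasing = TRUE)[seq_len(n_chromosomes)]
  loc <- markers[category == "L" & scaffold %in% names(lens)]
  labeled <- unique(loc$scaffold)
  src <- if ("source" %in% names(loc)) loc$source else rep("marker", nrow(loc))
  src_levels <- unique(src)
  src_cols <- setNames(colorRampPalette(
    c("#E41A1C", "#377EB8", "#4DAF4A", "#984EA3", "#FF7F00"))(
      max(length(src_levels), 1L)), src_levels)
  open_device(file, format)
  on.exit(dev.off())
  ypos <- chrom_bar_canvas(lens, "STR marker localization")
  for (id in names(lens)) {
    y <- ypos[[id]]
    rect(0, y - 0.3, lens[[id]], y + 0.3,
         col = if (id %in% labeled) "#FFFFFF" else "#D9D9D9",
         border = "#636363")
  }
  if (nrow(loc))
    points((loc$start + loc$end) / 2, ypos[loc$scaffold], pch = 19,
           col = src_cols[src], cex = 1.1)
  if (length(src_levels))
    legend("bottomright", legend = src_levels, col = src_cols, pch = 19,
           cex = 0.7, title = "source")
  invisible(list(path = file, labeled = labeled,
                 unlabeled = setdiff(names(lens), labeled)))
}

#' Render a figure from a plot specification
#'
#' @param spec list with `kind` (one of `het_heatmap`, `summary_boxplot`,
#'   `coverage_track`, `marker_map`), `path`, optional `format`,
#'   `thresholds`, `clip`, `n_chromosomes`
#' @param data the module output the figure kind needs (window track,
#'   subsets list, coverage profile, or list(markers, lengths))
#' @return the output path, invisibly
#' @export
render <- function(spec, data) {
  stopifnot(is.list(spec), !is.null(spec$kind), !is.null(spec$path))
  if (!is.null(spec$thresholds) &&
      is.unsorted(spec$thresholds, strictly = TRUE))
    stopf("thresholds must be strictly increasing")
  fmt <- spec$format %||% "png"
  switch(spec$kind,
    het_heatmap = plot_het_heatmap(data, spec$path,
                                   breaks = spec$thresholds %||% c(0.1, 0.75),
                                   n_chromosomes = spec$n_chromosomes,
                                   format = fmt),
    summary_boxplot = plot_summary_boxplot(data, spec$path, clip = spec$clip,
                                           format = fmt),
    coverage_track = plot_coverage_track(data, spec$path, format = fmt),
    marker_map = plot_marker_map(data$markers, data$lengths,
                                 spec$n_chromosomes %||% length(data$lengths),
                                 spec$path, format = fmt),
    stopf("unknown figure kind '%s'", spec$kind))
  invisible(spec$path)
}
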
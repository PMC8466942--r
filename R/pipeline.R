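#' Run the full synthetic-data pipeline
#'
#' Simulates a genome, variants, depth and an STR panel, writes the fixtures
#' (FASTA, VCF, bedGraph, primer TSV) into `out_dir`, then runs the analysis
#' stages end to end: quality + coverage filtering, SNP/indel split,
#' heterozygosity windows, X/PAR detection, region comparisons, STR mapping
#' and figure rendering. All randomness derives from `config$seed`, so two
#' runs with the same config produce byte-identical text outputs.
#'
#' @param config a `sim_config`
#' @param out_dir output directory (created if needed)
#' @param sex simulated individual's sex (`"male"` enables X/PAR detection)
#' @param window_sizes heterozygosity window widths in bases
#' @param plots render figures too (requires a working graphics device)
#' @return (invisibly) list of result objects and output paths
#' @export
run_pipeline <- function(config = sim_config(), out_dir, sex = "male",
                         window_sizes = c(1e5, 1e6), plots = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(out_dir, ...)

  genome <- simulate_genome(config)
  panel_sim <- simulate_panel(config, genome)
  genome$chromosome <- panel_sim$genome      # panel planting edits sequence
  vars <- simulate_variants(config, genome, sex = sex)
  track <- simulate_depth(config, genome, sex = sex)

  write_fasta(genome$chromosome, p("chromosome.fa"))
  write_fasta(genome$draft, p("draft.fa"))
  lens <- scaffold_lengths(genome$chromosome)
  write_sim_vcf(vars$records, lens, p("calls.vcf"))
  write_bedgraph(track, p("depth.bedgraph"))
  fwrite(panel_sim$panel, p("panel.tsv"), sep = "\t")

  # assembly comparison
  m_draft <- compute_assembly_metrics(genome$draft)
  m_chrom <- compute_assembly_metrics(genome$chromosome)
  cmp <- write_assembly_report("synthetic", m_draft, m_chrom,
                               p("assembly_report.tsv"))

  # variant filtering
  filt <- suppressWarnings(
    filter_vcf_file(p("calls.vcf"), track, p("filtered.vcf"),
                    bed_path = p("coverage_mask.bed")))
  snps <- split_snp_indel(filt$records)$snps
  het_snps <- snps[is_het(snps$gt)]

  # heterozygosity windows
  tracks <- lapply(window_sizes, function(ws)
    het_density(het_snps[, .(scaffold, pos)], lens, ws))
  names(tracks) <- paste0("win", window_sizes)
  for (i in seq_along(tracks))
    write_window_track(tracks[[i]],
                       p(sprintf("het_windows_%d.tsv", window_sizes[i])))

  # X and PAR from depth (male only)
  x_id <- NULL; par <- NULL; tests <- NULL
  if (sex == "male") {
    prof1m <- window_median_depth(track, 1e6)
    x_id <- identify_x(prof1m, sex = "male")
    par <- detect_par(track, x_id)
    write_par_bed(par, p("par.bed"))
    fwrite(window_median_depth(track, 1e4), p("coverage_profile.tsv"),
           sep = "\t")
    subsets <- subset_windows(tracks[[1L]], x_id, par)
    tests <- run_region_comparisons(list(sample1 = subsets),
                                    c(sample1 = sex))
    fwrite(tests, p("region_tests.tsv"), sep = "\t")
  }

  # STR mapping
  calls <- str_map(genome$chromosome, panel_sim$panel)
  mtab <- marker_table(calls)
  mtab <- merge(mtab, panel_sim$panel[, .(marker_id, source)],
                by = "marker_id", sort = FALSE)
  fwrite(mtab, p("markers.tsv"), sep = "\t")
  rep_ <- panel_report(calls, genome$chromosome,
                       n_chromosomes = config$n_autosomes + 1L)
  fwrite(data.table(n_localized = rep_$n_localized,
                    n_not_amplified = rep_$n_not_amplified,
                    n_declined = rep_$n_declined,
                    n_chromosomes = rep_$n_chromosomes,
                    n_chrom_with_markers = rep_$n_chrom_with_markers,
                    overall_density = rep_$overall_density),
         p("panel_summary.tsv"), sep = "\t")

  if (plots) {
    # heatmap at the coarsest window size that still has complete windows
    nonempty <- which(vapply(tracks, nrow, 0L) > 0)
    if (length(nonempty))
      render(list(kind = "het_heatmap", path = p("fig_heatmap.png")),
             tracks[[max(nonempty)]])
    if (!is.null(par)) {
      render(list(kind = "coverage_track", path = p("fig_coverage.png")),
             window_median_depth(track, 1e4))
      render(list(kind = "summary_boxplot", path = p("fig_boxplot.png"),
                  clip = 2),
             subset_windows(tracks[[1L]], x_id, par))
    }
    render(list(kind = "marker_map", path = p("fig_markers.png"),
                n_chromosomes = config$n_autosomes + 1L),
           list(markers = mtab, lengths = lens))
  }

  invisible(list(genome = genome, variants = vars, depth = track,
                 comparison = cmp, filtered = filt, tracks = tracks,
                 x_scaffold = x_id, par = par, tests = tests,
                 marker_calls = calls, panel = panel_sim, out_dir = out_dir))
}

cli_usage <- function() {
  cat("usage: chromdiv <command> [options]\n\n",
      "commands:\n",
      "  simulate    --out-dir DIR [--seed N] [--sex male|female]\n",
      "  asm-stats   --draft FA --chrom FA --out TSV [--species NAME]\n",
      "  filter-vcf  --vcf VCF --depth BEDGRAPH --out VCF [--bed BED]\n",
      "  het-windows --vcf VCF --fasta FA --window N [--window N] --out-prefix P\n",
      "  find-x-par  --depth BEDGRAPH --fasta FA --sex male --out-prefix P\n",
      "  region-test --windows TSV --x-scaffold ID --par BED [--alpha A] --out TSV\n",
      "  str-map     --panel TSV --fasta FA --n-chromosomes N --out-prefix P\n",
      "  plot        --kind KIND --windows TSV --out IMG\n", sep = "")
}

cli_opt <- function(args, name, default = NULL, required = FALSE,
                    multiple = FALSE) {
  hits <- which(args == paste0("--", name))
  if (!length(hits)) {
    if (required) stopf("missing required option --%s", name)
    return(default)
  }
  vals <- args[hits + 1L]
  if (anyNA(vals)) stopf("option --%s needs a value", name)
  if (multiple) vals else vals[length(vals)]
}

#' Command-line entry point
#'
#' Dispatches the `chromdiv` subcommands (see `exec/chromdiv`). Exposed as a
#' function so the interface is scriptable and testable from R.
#'
#' @param args character vector of command-line arguments
#' @return exit status (0 on success), invisibly
#' @export
chromdiv_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) { cli_usage(); return(invisible(1L)) }
  cmd <- args[1L]; rest <- args[-1L]
  switch(cmd,
    simulate = {
      seed <- as.integer(cli_opt(rest, "seed", "1"))
      run_pipeline(sim_config(seed = seed),
                   cli_opt(rest, "out-dir", required = TRUE),
                   sex = cli_opt(rest, "sex", "male"),
                   plots = !is.null(grDevices::png))
    },
    `asm-stats` = {
      draft <- compute_assembly_metrics(
        read_fasta(cli_opt(rest, "draft", required = TRUE)))
      chrom <- compute_assembly_metrics(
        read_fasta(cli_opt(rest, "chrom", required = TRUE)))
      write_assembly_report(cli_opt(rest, "species", "sample"), draft, chrom,
                            cli_opt(rest, "out", required = TRUE))
    },
    `filter-vcf` = {
      track <- read_bedgraph(cli_opt(rest, "depth", required = TRUE))
      filter_vcf_file(cli_opt(rest, "vcf", required = TRUE), track,
                      cli_opt(rest, "out", required = TRUE),
                      bed_path = cli_opt(rest, "bed"))
    },
    `het-windows` = {
      lens <- scaffold_lengths(read_fasta(cli_opt(rest, "fasta",
                                                  required = TRUE)))
      rec <- read_vcf(cli_opt(rest, "vcf", required = TRUE))
      snps <- split_snp_indel(rec)$snps
      hs <- snps[is_het(snps$gt)]
      prefix <- cli_opt(rest, "out-prefix", required = TRUE)
      for (ws in as.numeric(cli_opt(rest, "window", "100000",
                                    multiple = TRUE))) {
        tr <- het_density(hs[, .(scaffold, pos)], lens, ws)
        write_window_track(tr, sprintf("%s.win%d.tsv", prefix, as.integer(ws)))
      }
    },
    `find-x-par` = {
      lens <- scaffold_lengths(read_fasta(cli_opt(rest, "fasta",
                                                  required = TRUE)))
      track <- read_bedgraph(cli_opt(rest, "depth", required = TRUE), lens)
      x_id <- identify_x(window_median_depth(track, 1e6),
                         sex = cli_opt(rest, "sex", "male"))
      par <- detect_par(track, x_id)
      prefix <- cli_opt(rest, "out-prefix", required = TRUE)
      write_par_bed(par, paste0(prefix, ".par.bed"))
      fwrite(window_median_depth(track, 1e4),
             paste0(prefix, ".coverage_profile.tsv"), sep = "\t")
    },
    `region-test` = {
      win <- fread(cli_opt(rest, "windows", required = TRUE))
      setnames(win, "snps_per_kbp", "value", skip_absent = TRUE)
      x_id <- cli_opt(rest, "x-scaffold", required = TRUE)
      bed <- fread(cli_opt(rest, "par", required = TRUE), header = FALSE)
      par <- par_call(x_id, data.table(start = bed$V2, end = bed$V3))
      subs <- subset_windows(win, x_id, par)
      res <- run_region_comparisons(list(sample = subs),
                                    c(sample = cli_opt(rest, "sex", "female")),
                                    alpha = as.numeric(cli_opt(rest, "alpha",
                                                               "0.01")))
      fwrite(res, cli_opt(rest, "out", required = TRUE), sep = "\t")
    },
    `str-map` = {
      asm <- read_fasta(cli_opt(rest, "fasta", required = TRUE))
      panel <- read_primer_panel(cli_opt(rest, "panel", required = TRUE))
      calls <- str_map(asm, panel)
      prefix <- cli_opt(rest, "out-prefix", required = TRUE)
      fwrite(marker_table(calls), paste0(prefix, ".markers.tsv"), sep = "\t")
      nchr <- as.integer(cli_opt(rest, "n-chromosomes",
                                 as.character(length(asm$ids))))
      rep_ <- panel_report(calls, asm, nchr)
      fwrite(data.table(n_localized = rep_$n_localized,
                        n_not_amplified = rep_$n_not_amplified,
                        n_declined = rep_$n_declined,
                        n_chromosomes = rep_$n_chromosomes,
                        n_chrom_with_markers = rep_$n_chrom_with_markers,
                        overall_density = rep_$overall_density),
             paste0(prefix, ".summary.tsv"), sep = "\t")
    },
    plot = {
      win <- fread(cli_opt(rest, "windows", required = TRUE))
      setnames(win, "snps_per_kbp", "value", skip_absent = TRUE)
      setattr(win, "class", c("window_track", class(win)))
      render(list(kind = cli_opt(rest, "kind", "het_heatmap"),
                  path = cli_opt(rest, "out", required = TRUE)), win)
    },
    { cli_usage(); stopf("unknown command '%s'", cmd) })
  invisible(0L)
}
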
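#' Simulation configuration
#'
#' The defaults describe a desk-scale diploid genome that keeps the
#' proportions of the mammalian systems this package targets: several
#' autosomes plus an X carrying a terminal pseudoautosomal region (PAR),
#' spatially heterogeneous heterozygosity (baseline with a hotspot and a
#' long cold/homozygous stretch per autosome), elevated PAR heterozygosity,
#' a hemizygous male X body, sequencing depth around 30x with per-base
#' Poisson noise, and a heavily fragmented draft counterpart.
#'
#' @param seed RNG seed used by all generators
#' @param n_autosomes number of autosomes
#' @param autosome_length,x_length,par_length lengths in bases; the PAR sits
#'   at the terminal end of the X
#' @param het_rate_profile SNPs/kbp by region class: `autosome`, `hotspot`,
#'   `coldspot`, `par`, `x_body_female` (the male X body rate is 0,
#'   hemizygous)
#' @param hotspot_fraction,coldspot_fraction fraction of each autosome
#'   covered by its hotspot / coldspot
#' @param mean_depth mean sequencing depth (autosomes and PAR; male X body
#'   is at half this)
#' @param depth_noise `"poisson"` or `"none"`
#' @param overdispersion optional negative-binomial size parameter; when
#'   set, depth noise is overdispersed instead of Poisson
#' @param draft_fragmentation target scaffold N50 (bases) of the degraded
#'   draft assembly
#' @param gap_run length of the N run inserted at each draft junction
#' @param qual_violation_rate per-field probability that a simulated variant
#'   record violates one of the QUAL/DP/GQ/SP filter thresholds
#' @param indel_rate,homalt_rate fractions of records emitted as indels /
#'   homozygous-alternative genotypes
#' @param primer_length,amplicon_span primer and planted amplicon geometry
#' @return a `sim_config` list
#' @export
sim_config <- function(seed = 1L,
                       n_autosomes = 4L,
                       autosome_length = 2e6,
                       x_length = 2e6,
                       par_length = 3e5,
                       het_rate_profile = c(autosome = 1.0, hotspot = 2.0,
                                            coldspot = 0.1, par = 1.3,
                                            x_body_female = 0.5),
                       hotspot_fraction = 0.1,
                       coldspot_fraction = 0.15,
                       mean_depth = 30,
                       depth_noise = c("poisson", "none"),
                       overdispersion = NULL,
                       draft_fragmentation = 2e5,
                       gap_run = 100L,
                       qual_violation_rate = 0.05,
                       indel_rate = 0.05,
                       homalt_rate = 0.05,
                       primer_length = 24L,
                       amplicon_span = 300L) {
  depth_noise <- match.arg(depth_noise)
  stopifnot(par_length < x_length, par_length >= 1e5,
            all(het_rate_profile >= 0), mean_depth > 0,
            draft_fragmentation > 0)
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate a chromosome-level assembly and its fragmented draft
#'
#' Autosomes `auto1..autoN` plus `chrX`; the draft is produced from the same
#' sequence by cutting at random breakpoints until the scaffold N50 is near
#' `draft_fragmentation` and splitting each draft scaffold internally with
#' an N gap at the junction, so the draft's non-N content equals the
#' chromosome-level sequence exactly. Deterministic given `config$seed`.
#'
#' @param config a `sim_config`
#' @return list: `chromosome` and `draft` (`genome_assembly`s) and `truth`
#'   (PAR interval on chrX; fragment map draft scaffold -> chromosome span)
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  ids <- c(paste0("auto", seq_len(config$n_autosomes)), "chrX")
  lens <- c(rep(config$autosome_length, config$n_autosomes), config$x_length)
  seqs <- vapply(lens, random_dna, "")
  names(seqs) <- ids
  chrom <- genome_assembly(seqs)

  target <- config$draft_fragmentation
  if (target >= max(lens)) stopf("draft_fragmentation target not below chromosome length")
  frags <- list(); k <- 0L
  for (i in seq_along(ids)) {
    pos <- 0
    while (pos < lens[i]) {
      # exponential piece lengths; length-biased median ~ 1.678 x mean
      piece <- max(1000, round(stats::rexp(1, rate = 1.678 / target)))
      piece <- min(piece, lens[i] - pos)
      k <- k + 1L
      frags[[k]] <- data.table(draft_scaffold = sprintf("scf_%04d", k),
                               chrom = ids[i], chrom_start = pos,
                               chrom_end = pos + piece)
      pos <- pos + piece
    }
  }
  fmap <- rbindlist(frags)
  gap <- strrep("N", config$gap_run)
  draft_seqs <- vapply(seq_len(nrow(fmap)), function(j) {
    s <- as.character(subseq(chrom$seq[[fmap$chrom[j]]],
                             fmap$chrom_start[j] + 1L, fmap$chrom_end[j]))
    w <- nchar(s)
    if (w >= 2000) {                      # internal junction gap
      cut <- sample(1000:(w - 1000), 1L)
      s <- paste0(substr(s, 1L, cut), gap, substr(s, cut + 1L, w))
    }
    s
  }, "")
  names(draft_seqs) <- fmap$draft_scaffold
  draft <- genome_assembly(draft_seqs)
  list(chromosome = chrom, draft = draft,
       truth = list(par = data.table(scaffold = "chrX",
                                     start = config$x_length - config$par_length,
                                     end = config$x_length),
                    fragments = fmap))
}

# region table (scaffold, start, end, class, rate) for a given sex
rate_regions <- function(config, sex) {
  p <- config$het_rate_profile
  rows <- list()
  for (i in seq_len(config$n_autosomes)) {
    len <- config$autosome_length
    hot_len <- round(config$hotspot_fraction * len)
    cold_len <- round(config$coldspot_fraction * len)
    hot_start <- sample.int(len - hot_len - cold_len - 1L, 1L)
    cold_start <- hot_start + hot_len +
      sample.int(max(len - hot_start - hot_len - cold_len, 1L), 1L) - 1L
    cold_start <- min(cold_start, len - cold_len)
    id <- paste0("auto", i)
    rows[[id]] <- data.table(
      scaffold = id,
      start = c(0, hot_start, hot_start + hot_len, cold_start, cold_start + cold_len),
      end = c(hot_start, hot_start + hot_len, cold_start, cold_start + cold_len, len),
      class = c("autosome", "hotspot", "autosome", "coldspot", "autosome"))
  }
  body_rate_class <- if (sex == "male") "x_body_male" else "x_body_female"
  rows[["chrX"]] <- data.table(
    scaffold = "chrX",
    start = c(0, config$x_length - config$par_length),
    end = c(config$x_length - config$par_length, config$x_length),
    class = c(body_rate_class, "par"))
  reg <- rbindlist(rows)[end > start]
  rates <- c(p, x_body_male = 0)
  reg[, rate := rates[class]]
  reg[]
}

#' Simulate heterozygous variant calls for one individual
#'
#' SNPs are placed by an inhomogeneous Poisson process whose piecewise
#' constant intensity follows the configured region rates (autosome
#' baseline / hotspot / coldspot / PAR / X body; the male X body is
#' hemizygous, rate 0). QUAL/DP/GQ/SP are drawn from passing distributions
#' except that each field independently violates its filter threshold with
#' probability `qual_violation_rate`; a configured fraction of records are
#' indels or homozygous-alternative.
#'
#' @param config a `sim_config`
#' @param genome output of [simulate_genome()]
#' @param sex `"male"` or `"female"`
#' @param seed RNG seed (defaults to `config$seed + 1`)
#' @return list: `records` (variant truth table with per-record flags
#'   `is_snp`, `is_het`, `pass_quality`, `region`) and `regions` (the rate
#'   table used)
#' @export
simulate_variants <- function(config, genome, sex = c("female", "male"),
                              seed = config$seed + 1L) {
  sex <- match.arg(sex)
  set.seed(seed)
  reg <- rate_regions(config, sex)
  asm <- genome$chromosome
  recs <- list()
  for (i in seq_len(nrow(reg))) {
    len <- reg$end[i] - reg$start[i]
    n <- rpois(1L, reg$rate[i] / 1000 * len)
    if (n == 0) next
    n <- min(n, len)
    pos <- reg$start[i] + sample.int(len, n)   # 1-based, unique within region
    ref <- strsplit(as.character(subseq(asm$seq[[reg$scaffold[i]]],
                                        min(pos), max(pos))), "")[[1]][pos - min(pos) + 1L]
    alt <- vapply(ref, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L), "")
    recs[[i]] <- data.table(scaffold = reg$scaffold[i], pos = pos, ref = ref,
                            alt = alt, region = reg$class[i])
  }
  rec <- rbindlist(recs)
  if (!nrow(rec)) return(list(records = rec, regions = reg))
  setorder(rec, scaffold, pos)
  n <- nrow(rec)
  v <- config$qual_violation_rate
  # field values: passing draws, with independent per-field violations
  rec[, qual := round(runif(n, 30, 200), 1)]
  rec[, dp := pmax(5L, rpois(n, config$mean_depth))]
  rec[, gq := sample(30:99, n, replace = TRUE)]
  rec[, sp := sample(0:30, n, replace = TRUE)]
  viol_q <- runif(n) < v; viol_d <- runif(n) < v
  viol_g <- runif(n) < v; viol_s <- runif(n) < v
  rec[viol_q, qual := round(runif(sum(viol_q), 0, 19.9), 1)]
  rec[viol_d, dp := sample(0:4, sum(viol_d), replace = TRUE)]
  rec[viol_g, gq := sample(0:19, sum(viol_g), replace = TRUE)]
  rec[viol_s, sp := sample(61:99, sum(viol_s), replace = TRUE)]
  rec[, pass_quality := !(viol_q | viol_d | viol_g | viol_s)]
  is_indel <- runif(n) < config$indel_rate
  rec[is_indel, alt := paste0(alt,
                              sample(c("A", "C", "G", "T"), sum(is_indel),
                                     replace = TRUE))]
  rec[, is_snp := !is_indel]
  is_hom <- runif(n) < config$homalt_rate
  rec[, gt := ifelse(is_hom, "1/1", "0/1")]
  rec[, is_het := !is_hom]
  list(records = rec[], regions = reg)
}

#' Write simulated variant records as a VCF file
#'
#' Emits a minimal single-sample VCF 4.2 with QUAL and GT/DP/GQ/SP FORMAT
#' fields, suitable for [read_vcf()] and bcftools.
#'
#' @param records record table from [simulate_variants()]
#' @param lengths named scaffold lengths (for contig header lines)
#' @param path output path
#' @param sample_name sample column name
#' @return `path`, invisibly
#' @export
write_sim_vcf <- function(records, lengths, path, sample_name = "sample1") {
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s,length=%d>", names(lengths),
                   as.integer(lengths)),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
           "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
           "##FORMAT=<ID=SP,Number=1,Type=Integer,Description=\"Phred strand bias\">",
           paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
                  sample_name))
  body <- sprintf("%s\t%d\t.\t%s\t%s\t%s\t.\t.\tGT:DP:GQ:SP\t%s:%d:%d:%d",
                  records$scaffold, records$pos, records$ref, records$alt,
                  format(records$qual, trim = TRUE), records$gt,
                  as.integer(records$dp), as.integer(records$gq),
                  as.integer(records$sp))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Simulate a per-base read-depth track
#'
#' Autosomes and the PAR are at `mean_depth`; the male X body is at half
#' depth (hemizygous); female X is indistinguishable from autosomes.
#' Per-base noise is Poisson (or negative binomial when `overdispersion` is
#' set), or disabled for an exact step function.
#'
#' @param config a `sim_config`
#' @param genome output of [simulate_genome()]
#' @param sex `"male"` or `"female"`
#' @param seed RNG seed (defaults to `config$seed + 2`)
#' @return a `depth_track`
#' @export
simulate_depth <- function(config, genome, sex = c("male", "female"),
                           seed = config$seed + 2L) {
  sex <- match.arg(sex)
  set.seed(seed)
  lens <- scaffold_lengths(genome$chromosome)
  par_start <- config$x_length - config$par_length
  draw <- function(n, m) {
    if (config$depth_noise == "none") rep(m, n)
    else if (!is.null(config$overdispersion))
      rnbinom(n, size = config$overdispersion, mu = m)
    else rpois(n, m)
  }
  depths <- lapply(names(lens), function(id) {
    if (id == "chrX" && sex == "male") {
      c(draw(par_start, config$mean_depth / 2),
        draw(config$par_length, config$mean_depth))
    } else {
      draw(lens[[id]], config$mean_depth)
    }
  })
  names(depths) <- names(lens)
  depth_track(depths)
}

# -- fast window-level depth simulation -------------------------------------
#
# Sampling the per-base Poisson track and then taking 10-kbp window medians
# is equivalent in distribution to sampling, for each window, the counts of
# each depth value from Multinomial(window_size, Poisson pmf) and reading
# the median off the counts. This exact shortcut makes hundreds of
# genome-scale replicates affordable; the detector consumes the same
# window-median profile either way.

median_from_tab <- function(counts, values) {
  n <- sum(counts)
  cs <- cumsum(counts)
  lo <- values[which(cs >= (n + 1) %/% 2)[1L]]
  hi <- values[which(cs >= n %/% 2 + 1L)[1L]]
  if (n %% 2 == 1L) lo else (lo + hi) / 2
}

#' Simulate a male X window-median depth profile without per-base draws
#'
#' Returns exactly the inputs [detect_par_core()] consumes: per-window
#' median depths along chrX (PAR at full depth, body at half) and a
#' whole-genome median that includes the autosomes, drawn from the exact
#' sampling distribution implied by per-base Poisson noise (see source for
#' the multinomial-tabulation argument).
#'
#' @param x_length,par_length X and terminal-PAR lengths (bases)
#' @param autosome_bases total autosomal bases contributing to the genome
#'   median
#' @param mean_depth autosomal mean depth
#' @param window_size window width (default 10 kbp)
#' @return list: `medians`, `starts`, `ends`, `genome_median`, `par_start`
#' @export
simulate_depth_profile <- function(x_length, par_length, autosome_bases,
                                   mean_depth, window_size = 1e4) {
  stopifnot(par_length < x_length, x_length %% window_size == 0)
  vmax <- max(30, ceiling(mean_depth + 8 * sqrt(mean_depth)))
  vals <- 0:vmax
  p_full <- stats::dpois(vals, mean_depth)
  p_half <- stats::dpois(vals, mean_depth / 2)
  nw <- x_length / window_size
  starts <- (seq_len(nw) - 1) * window_size
  ends <- starts + window_size
  par_start <- x_length - par_length
  # per-window mixture weights of half-depth bases
  half_frac <- pmin(pmax((par_start - starts) / window_size, 0), 1)
  medians <- numeric(nw)
  tab_total <- numeric(length(vals))
  for (i in seq_len(nw)) {
    pr <- half_frac[i] * p_half + (1 - half_frac[i]) * p_full
    tab <- rmultinom(1L, window_size, pr)[, 1L]
    medians[i] <- median_from_tab(tab, vals)
    tab_total <- tab_total + tab
  }
  tab_auto <- rmultinom(1L, autosome_bases, p_full)[, 1L]
  gm <- weighted_median_counts(vals, tab_total + tab_auto)
  list(medians = medians, starts = starts, ends = ends,
       genome_median = gm, par_start = par_start)
}

# -- STR marker panel planting ----------------------------------------------

plant_site <- function(asm, scaffold, at, seqs) {
  # overwrite the scaffold sequence at the 0-based offsets in names(seqs)
  s <- asm$seq[[scaffold]]
  for (k in seq_along(seqs)) {
    off <- as.integer(names(seqs)[k])
    s <- replaceAt(s, IRanges(off + 1L, off + nchar(seqs[k])),
                   DNAString(seqs[k]))
  }
  asm$seq[[scaffold]] <- s
  asm
}

scenario_specs <- function() {
  # (top fwd_mm, top rev_mm, decoy fwd_mm, decoy rev_mm or NA = no decoy)
  list(
    L1      = list(top = c(0, 0), decoy = NULL,      category = "L", group = 1L),
    L2_mm   = list(top = c(0, 0), decoy = c(2, 2),   category = "L", group = 2L),
    L2_tm   = list(top = c(1, 0), decoy = c(2, 2),   category = "L", group = 2L),
    D_sep   = list(top = c(1, 1), decoy = c(2, 1),   category = "D", group = NA_integer_),
    D_mm4   = list(top = c(4, 0), decoy = NULL,      category = "D", group = NA_integer_),
    D_single= list(top = NULL,    decoy = NULL,      category = "D", group = NA_integer_),
    no_amp  = list(top = NULL,    decoy = NULL,      category = "NA", group = NA_integer_)
  )
}

#' Plant an STR primer panel with known truth into a simulated genome
#'
#' Generates one marker per scenario, spanning the classification space:
#' a unique exact target (L group 1), a target plus a decoy separated by
#' MM >= 2 or TM >= 3 (L group 2), decoys just inside the separation
#' boundary (declined), a site at the MM = 4 allowance (declined), a
#' single-primer FF product only (declined, not "no amplification"), and
#' primers with no target at all. Decoy and imperfect sites are written
#' into the genome by substring replacement, so the returned (modified)
#' assembly must be the one used downstream. Site uniqueness is verified
#' with [find_primer_sites()]; loci are re-drawn when the random background
#' happens to contain an extra binding site.
#'
#' @param config a `sim_config`
#' @param genome output of [simulate_genome()] (chromosome assembly is used)
#' @param scenarios scenario names to plant (each once by default); see
#'   source for the catalogue
#' @param seed RNG seed (defaults to `config$seed + 3`)
#' @return list: `genome` (modified assembly), `panel` (primer table),
#'   `truth` (expected category/group and planted coordinates per marker)
#' @export
simulate_panel <- function(config, genome,
                           scenarios = names(scenario_specs()),
                           seed = config$seed + 3L) {
  set.seed(seed)
  specs <- scenario_specs()
  stopifnot(all(scenarios %in% names(specs)))
  asm <- genome$chromosome
  plen <- config$primer_length
  span <- config$amplicon_span
  lens <- scaffold_lengths(asm)
  autos <- grep("^auto", names(lens), value = TRUE)
  used <- data.table(scaffold = character(0), start = numeric(0),
                     end = numeric(0))
  pick_locus <- function(width) {
    for (try in 1:200) {
      sc <- sample(autos, 1L)
      at <- sample.int(lens[[sc]] - width - 1L, 1L)
      clash <- used[scaffold == sc & at < end + 2000 & at + width > start - 2000]
      if (!nrow(clash)) {
        used <<- rbind(used, data.table(scaffold = sc, start = at,
                                        end = at + width))
        return(list(scaffold = sc, at = at))
      }
    }
    stopf("could not place marker locus")
  }
  panel <- list(); truth <- list()
  for (sc_name in scenarios) {
    spec <- specs[[sc_name]]
    ok <- FALSE
    for (attempt in 1:25) {
      if (sc_name == "no_amp") {
        fwd <- random_dna(plen); rev <- random_dna(plen)
        cand_asm <- asm
        locus <- list(scaffold = NA_character_, at = NA_integer_)
      } else if (sc_name == "D_single") {
        locus <- pick_locus(span)
        fwd <- random_dna(plen); rev <- random_dna(plen)
        # plant fwd and its facing reverse-complement; rev primer nowhere
        edits <- setNames(c(fwd, revcomp_chr(fwd)),
                          c(locus$at, locus$at + span - plen))
        cand_asm <- plant_site(asm, locus$scaffold, locus$at, edits)
      } else {
        locus <- pick_locus(span)
        fwd <- random_dna(plen); rev <- random_dna(plen)
        top_f <- if (spec$top[1] > 0) mutate_seq(fwd, spec$top[1]) else fwd
        top_r <- if (spec$top[2] > 0) mutate_seq(rev, spec$top[2]) else rev
        edits <- setNames(c(top_f, revcomp_chr(top_r)),
                          c(locus$at, locus$at + span - plen))
        cand_asm <- plant_site(asm, locus$scaffold, locus$at, edits)
        if (!is.null(spec$decoy)) {
          dloc <- pick_locus(span)
          d_f <- mutate_seq(fwd, spec$decoy[1])
          d_r <- mutate_seq(rev, spec$decoy[2])
          edits2 <- setNames(c(d_f, revcomp_chr(d_r)),
                             c(dloc$at, dloc$at + span - plen))
          cand_asm <- plant_site(cand_asm, dloc$scaffold, dloc$at, edits2)
        }
      }
      # verify the site lists are exactly the planted ones
      n_f <- nrow(find_primer_sites(cand_asm, fwd))
      n_r <- nrow(find_primer_sites(cand_asm, rev))
      expected_f <- switch(sc_name, no_amp = 0L, D_single = 2L,
                           if (is.null(spec$decoy)) 1L else 2L)
      expected_r <- switch(sc_name, no_amp = 0L, D_single = 0L,
                           if (is.null(spec$decoy)) 1L else 2L)
      if (n_f == expected_f && n_r == expected_r) { ok <- TRUE; break }
    }
    if (!ok) stopf("failed to plant scenario '%s' without background hits",
                   sc_name)
    asm <- cand_asm
    mid <- paste0("mk_", sc_name)
    panel[[mid]] <- data.table(marker_id = mid, forward = fwd, reverse = rev,
                               source = "synthetic")
    truth[[mid]] <- data.table(marker_id = mid, scenario = sc_name,
                               category = spec$category, group = spec$group,
                               scaffold = locus$scaffold,
                               start = locus$at)
  }
  list(genome = genome_assembly(asm$seq), panel = rbindlist(panel),
       truth = rbindlist(truth))
}
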
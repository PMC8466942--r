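#' Read an STR primer panel from TSV
#'
#' Columns: `marker_id`, `forward`, `reverse`, and optionally `source`
#' (species or publication the marker was developed in). Primers may contain
#' IUPAC ambiguity codes; length must be at least 10 nt and marker ids must
#' be unique.
#'
#' @param path TSV file
#' @return data.table panel
#' @export
read_primer_panel <- function(path) {
  panel <- fread(path, sep = "\t", colClasses = "character")
  need <- c("marker_id", "forward", "reverse")
  if (!all(need %in% names(panel)))
    stopf("panel must have columns %s", paste(need, collapse = ", "))
  if (!"source" %in% names(panel)) panel[, source := NA_character_]
  panel[, `:=`(forward = toupper(forward), reverse = toupper(reverse))]
  validate_panel(panel)
  panel[]
}

validate_panel <- function(panel) {
  if (anyDuplicated(panel$marker_id))
    stopf("duplicate marker_id: %s",
          panel$marker_id[duplicated(panel$marker_id)][1L])
  for (i in seq_len(nrow(panel))) {
    for (p in c(panel$forward[i], panel$reverse[i])) {
      if (nchar(p) < 10L)
        stopf("primer of marker '%s' shorter than 10 nt", panel$marker_id[i])
      if (!is_iupac(p))
        stopf("primer of marker '%s' contains a non-IUPAC character",
              panel$marker_id[i])
    }
  }
  invisible(panel)
}

#' Find all binding sites of one primer in an assembly
#'
#' End-to-end (no indels) Hamming alignment on both strands with at most
#' `max_mismatch` mismatches. IUPAC ambiguity codes in the primer match any
#' base of their expansion set; an `N` in the genome matches nothing (it
#' always counts as a mismatch against a non-N primer base).
#'
#' @param assembly a `genome_assembly`
#' @param primer primer sequence (IUPAC allowed)
#' @param max_mismatch maximum allowed mismatches (default 4)
#' @return data.table of sites: `scaffold`, `start`, `end` (0-based
#'   half-open footprint on the plus strand), `strand` (`+` when the primer
#'   anneals in plus orientation, i.e. extends rightwards), `mismatches`
#' @export
find_primer_sites <- function(assembly, primer, max_mismatch = 4) {
  stopifnot(inherits(assembly, "genome_assembly"), nchar(primer) >= 1)
  primer <- toupper(primer)
  if (!is_iupac(primer)) stopf("primer contains a non-IUPAC character")
  fixed <- c(pattern = FALSE, subject = TRUE)
  pats <- list(`+` = DNAString(primer),
               `-` = reverseComplement(DNAString(primer)))
  rows <- list()
  for (i in seq_along(assembly$ids)) {
    subj <- assembly$seq[[i]]
    for (str_ in names(pats)) {
      m <- matchPattern(pats[[str_]], subj, max.mismatch = max_mismatch,
                        with.indels = FALSE, fixed = fixed)
      if (!length(m)) next
      mm <- neditStartingAt(pats[[str_]], subj, starting.at = start(m),
                            with.indels = FALSE, fixed = fixed)
      rows[[length(rows) + 1L]] <- data.table(
        scaffold = assembly$ids[i], start = start(m) - 1L, end = end(m),
        strand = str_, mismatches = as.integer(mm))
    }
  }
  if (!length(rows))
    return(data.table(scaffold = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      mismatches = integer(0)))
  out <- rbindlist(rows)
  setorder(out, scaffold, start, strand)
  out[]
}

#' Pair primer binding sites into candidate amplicons
#'
#' An amplicon arises when two sites on the same scaffold face each other
#' (upstream site on the plus strand, downstream site on the minus strand)
#' and the outermost span is within `[min_len, max_len]`. Products formed by
#' the forward and reverse primer are labelled `FR` (forward upstream) or
#' `RF` (reverse upstream); products of one primer with itself (`FF`, `RR`)
#' are emitted too but flagged `single_primer` and can never be localized.
#'
#' @param fwd_sites,rev_sites site tables from [find_primer_sites()] for the
#'   forward and reverse primer
#' @param min_len,max_len allowed amplicon span in bases (defaults 50-1000)
#' @return data.table of amplicons: `scaffold`, `start`, `end`, `length`
#'   (outermost primer-to-primer span), `orientation`, `fwd_mm`, `rev_mm`,
#'   `mm_score` (max), `tm_score` (sum), `single_primer`
#' @export
pair_amplicons <- function(fwd_sites, rev_sites, min_len = 50, max_len = 1000) {
  f <- copy(as.data.table(fwd_sites)); f[, primer := "F"]
  r <- copy(as.data.table(rev_sites)); r[, primer := "R"]
  sites <- rbind(f, r)
  if (!nrow(sites)) return(empty_amplicons())
  plus <- sites[strand == "+"]
  minus <- sites[strand == "-"]
  if (!nrow(plus) || !nrow(minus)) return(empty_amplicons())
  rows <- list()
  for (id in intersect(unique(plus$scaffold), unique(minus$scaffold))) {
    p <- plus[scaffold == id]; m <- minus[scaffold == id]
    grid <- CJ(i = seq_len(nrow(p)), j = seq_len(nrow(m)))
    span <- m$end[grid$j] - p$start[grid$i]
    ok <- p$start[grid$i] <= m$start[grid$j] & span >= min_len & span <= max_len
    if (!any(ok)) next
    grid <- grid[ok]; span <- span[ok]
    up <- p[grid$i]; down <- m[grid$j]
    ori <- paste0(up$primer, down$primer)
    ori2 <- ifelse(ori == "FR", "FR", ifelse(ori == "RF", "RF", ori))
    # mismatch attribution: primer-wise for two-primer products, by
    # upstream/downstream member for single-primer products
    fwd_mm <- ifelse(ori2 == "FR", up$mismatches,
                     ifelse(ori2 == "RF", down$mismatches, up$mismatches))
    rev_mm <- ifelse(ori2 == "FR", down$mismatches,
                     ifelse(ori2 == "RF", up$mismatches, down$mismatches))
    rows[[length(rows) + 1L]] <- data.table(
      scaffold = id, start = up$start, end = down$end, length = span,
      orientation = ori2, fwd_mm = fwd_mm, rev_mm = rev_mm,
      mm_score = pmax(fwd_mm, rev_mm), tm_score = fwd_mm + rev_mm,
      single_primer = !ori2 %in% c("FR", "RF"))
  }
  if (!length(rows)) return(empty_amplicons())
  out <- rbindlist(rows)
  setorder(out, scaffold, start)
  out[]
}

empty_amplicons <- function() {
  data.table(scaffold = character(0), start = integer(0), end = integer(0),
             length = integer(0), orientation = character(0),
             fwd_mm = integer(0), rev_mm = integer(0), mm_score = integer(0),
             tm_score = integer(0), single_primer = logical(0))
}

#' Rank amplicons from best to worst
#'
#' Stable ascending sort by (MM score, TM score, length): the classification
#' rules are defined on MM/TM separation, so mismatch scores are the primary
#' keys and span length breaks remaining ties.
#'
#' @param amplicons amplicon table from [pair_amplicons()]
#' @return the table reordered, best first
#' @export
rank_amplicons <- function(amplicons) {
  amplicons[order(mm_score, tm_score, length)]  # data.table order() is stable
}

#' Classify one STR marker from its amplicon set
#'
#' Categories: `NA` when no amplicon at all was produced; `L` (localized)
#' when the top-ranked amplicon is a two-primer (FR/RF) product with MM
#' score <= 3 and is either the only amplicon (group 1) or separated from
#' the second-ranked amplicon by MM difference >= 2 or TM difference >= 3
#' (group 2); `D` (declined) otherwise.
#'
#' @param marker_id marker label
#' @param amplicons amplicon table for this marker
#' @return a `marker_call` list: `marker_id`, `category` (`"NA"`, `"D"`,
#'   `"L"`), `group` (1, 2 or NA), `chosen` (top amplicon row or NULL),
#'   `amplicons` (ranked table)
#' @export
classify_marker <- function(marker_id, amplicons) {
  if (!nrow(amplicons)) {
    return(structure(list(marker_id = marker_id, category = "NA",
                          group = NA_integer_, chosen = NULL,
                          amplicons = amplicons),
                     class = "marker_call"))
  }
  ranked <- rank_amplicons(amplicons)
  top <- ranked[1L]
  ok_top <- top$orientation %in% c("FR", "RF") && top$mm_score <= 3
  category <- "D"; group <- NA_integer_; chosen <- NULL
  if (ok_top) {
    if (nrow(ranked) == 1L) {
      category <- "L"; group <- 1L; chosen <- top
    } else {
      second <- ranked[2L]
      if (second$mm_score - top$mm_score >= 2 ||
          second$tm_score - top$tm_score >= 3) {
        category <- "L"; group <- 2L; chosen <- top
      }
    }
  }
  structure(list(marker_id = marker_id, category = category, group = group,
                 chosen = chosen, amplicons = ranked),
            class = "marker_call")
}

#' @export
print.marker_call <- function(x, ...) {
  cat(sprintf("<marker_call> %s: %s%s, %d amplicon(s)\n", x$marker_id,
              x$category,
              if (!is.na(x$group)) paste0(" (group ", x$group, ")") else "",
              nrow(x$amplicons)))
  invisible(x)
}

#' In silico PCR of a whole primer panel against an assembly
#'
#' For each marker: find both primers' binding sites (at most `max_mismatch`
#' mismatches each), pair them into candidate amplicons within the length
#' bounds, rank, and classify.
#'
#' @param assembly a `genome_assembly`
#' @param panel primer panel (see [read_primer_panel()])
#' @param max_mismatch per-primer mismatch allowance
#' @param min_len,max_len amplicon span bounds
#' @return named list of `marker_call`s, one per marker
#' @export
str_map <- function(assembly, panel, max_mismatch = 4,
                    min_len = 50, max_len = 1000) {
  validate_panel(panel)
  calls <- vector("list", nrow(panel))
  names(calls) <- panel$marker_id
  for (i in seq_len(nrow(panel))) {
    fs <- find_primer_sites(assembly, panel$forward[i], max_mismatch)
    rs <- find_primer_sites(assembly, panel$reverse[i], max_mismatch)
    amps <- pair_amplicons(fs, rs, min_len, max_len)
    calls[[i]] <- classify_marker(panel$marker_id[i], amps)
  }
  calls
}

#' Flatten marker calls into a per-marker table
#'
#' @param calls list of `marker_call`s
#' @return data.table with category, group and the chosen amplicon's
#'   coordinates/scores (NA when not localized)
#' @export
marker_table <- function(calls) {
  rbindlist(lapply(calls, function(cl) {
    ch <- cl$chosen
    data.table(marker_id = cl$marker_id, category = cl$category,
               group = cl$group,
               scaffold = if (is.null(ch)) NA_character_ else ch$scaffold,
               start = if (is.null(ch)) NA_integer_ else ch$start,
               end = if (is.null(ch)) NA_integer_ else ch$end,
               length = if (is.null(ch)) NA_integer_ else ch$length,
               fwd_mm = if (is.null(ch)) NA_integer_ else ch$fwd_mm,
               rev_mm = if (is.null(ch)) NA_integer_ else ch$rev_mm,
               mm_score = if (is.null(ch)) NA_integer_ else ch$mm_score,
               tm_score = if (is.null(ch)) NA_integer_ else ch$tm_score)
  }))
}

#' Marker densities per chromosome
#'
#' @param n_localized count of localized (L) markers
#' @param n_chromosomes number of chromosome-length scaffolds
#' @param n_with_markers number of those carrying at least one L marker
#' @return list: `overall_density` (L per chromosome) and `labeled_density`
#'   (L per chromosome that carries markers)
#' @export
str_densities <- function(n_localized, n_chromosomes, n_with_markers) {
  stopifnot(n_chromosomes >= 1, n_with_markers <= n_chromosomes)
  list(overall_density = n_localized / n_chromosomes,
       labeled_density = if (n_with_markers > 0)
         n_localized / n_with_markers else 0)
}

#' Panel-level summary of marker calls
#'
#' The `n_chromosomes` longest scaffolds are designated C-scaffolds;
#' localized markers whose chosen amplicon lies on a smaller scaffold are
#' counted as unplaced.
#'
#' @param calls list of `marker_call`s
#' @param assembly the searched `genome_assembly`
#' @param n_chromosomes haploid chromosome number (C-scaffold count)
#' @return list with category counts, chromosomes with/without markers,
#'   `overall_density`, `labeled_density`, `n_unplaced`, and the C-scaffold
#'   marker counts table
#' @export
panel_report <- function(calls, assembly, n_chromosomes) {
  lens <- scaffold_lengths(assembly)
  if (n_chromosomes > length(lens))
    stopf("n_chromosomes (%d) exceeds scaffold count (%d)", n_chromosomes,
          length(lens))
  cscaf <- names(sort(lens, decreasing = TRUE))[seq_len(n_chromosomes)]
  tab <- marker_table(calls)
  n_l <- sum(tab$category == "L")
  placed <- tab[category == "L" & scaffold %in% cscaf]
  per_chrom <- data.table(scaffold = cscaf)
  cnt <- placed[, .N, by = scaffold]
  per_chrom <- merge(per_chrom, cnt, by = "scaffold", all.x = TRUE)
  per_chrom[is.na(N), N := 0L]
  n_with <- sum(per_chrom$N > 0)
  dens <- str_densities(n_l, n_chromosomes, max(n_with, 0L))
  list(n_localized = n_l,
       n_not_amplified = sum(tab$category == "NA"),
       n_declined = sum(tab$category == "D"),
       n_chromosomes = n_chromosomes,
       n_chrom_with_markers = n_with,
       n_chrom_without_markers = n_chromosomes - n_with,
       overall_density = dens$overall_density,
       labeled_density = if (n_with > 0) n_l / n_with else NA_real_,
       n_unplaced = n_l - nrow(placed),
       per_chromosome = per_chrom)
}
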
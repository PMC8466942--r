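#' Construct a genome assembly object
#'
#' An assembly is an ordered set of uniquely named scaffolds. Sequences are
#' stored uppercase; only `N` counts as gap sequence.
#'
#' @param seqs named character vector or `DNAStringSet` of scaffold sequences
#' @return an object of class `genome_assembly`
#' @export
genome_assembly <- function(seqs) {
  if (is.character(seqs)) seqs <- DNAStringSet(toupper(seqs))
  ids <- names(seqs)
  if (is.null(ids) || anyNA(ids) || any(ids == ""))
    stopf("every scaffold needs a name")
  if (anyDuplicated(ids))
    stopf("duplicate scaffold id: %s", ids[duplicated(ids)][1L])
  if (any(width(seqs) < 1L))
    stopf("empty scaffold: %s", ids[width(seqs) < 1L][1L])
  structure(list(seq = seqs, ids = ids), class = "genome_assembly")
}

#' @export
print.genome_assembly <- function(x, ...) {
  cat(sprintf("<genome_assembly> %d scaffolds, %s bp total\n",
              length(x$ids), format(sum(width(x$seq)), big.mark = ",")))
  invisible(x)
}

#' Scaffold lengths of an assembly
#' @param assembly a `genome_assembly`
#' @return named integer vector of lengths in bases
#' @export
scaffold_lengths <- function(assembly) {
  setNames(width(assembly$seq), assembly$ids)
}

#' Read a FASTA file into a genome assembly
#'
#' One scaffold per record; the scaffold id is the first whitespace-delimited
#' token of the header; sequence is uppercased. Duplicate ids and empty
#' records are rejected.
#'
#' @param path path to a FASTA file (wrapped or unwrapped lines)
#' @return a `genome_assembly`
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  first <- readLines(path, n = 1L)
  if (!length(first) || !startsWith(first, ">"))
    stopf("malformed FASTA (line 1 is not a header): %s", path)
  seqs <- tryCatch(readDNAStringSet(path),
                   error = function(e) stopf("FASTA parse error in %s: %s",
                                             path, conditionMessage(e)))
  if (!length(seqs)) stopf("no records in %s", path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (any(width(seqs) == 0L))
    stopf("empty FASTA record '%s' in %s", names(seqs)[width(seqs) == 0L][1L], path)
  genome_assembly(DNAStringSet(toupper(seqs)))
}

#' Write an assembly to FASTA
#' @param assembly a `genome_assembly`
#' @param path output path
#' @param width line wrap width
#' @return `path`, invisibly
#' @export
write_fasta <- function(assembly, path, width = 70L) {
  Biostrings::writeXStringSet(assembly$seq, path, width = width)
  invisible(path)
}

#' Scaffold N50 of a set of lengths
#'
#' N50 is the length L such that scaffolds of length >= L jointly cover at
#' least half of the total assembly length (scaffolds sorted descending; when
#' the cumulative sum reaches exactly 50%, that scaffold's length is the N50).
#'
#' @param lengths integer vector of scaffold lengths
#' @return N50 in bases
#' @export
n50 <- function(lengths) {
  stopifnot(length(lengths) > 0L, all(lengths >= 1))
  s <- sort(as.numeric(lengths), decreasing = TRUE)
  s[which(cumsum(s) >= sum(s) / 2)[1L]]
}

#' Summary statistics of an assembly
#'
#' @param assembly a `genome_assembly`
#' @return an `assembly_metrics` list: `total_length`, `gap_length` (count of
#'   `N` bases), `scaffold_n50`, `scaffold_count`
#' @export
compute_assembly_metrics <- function(assembly) {
  stopifnot(inherits(assembly, "genome_assembly"))
  w <- width(assembly$seq)
  gaps <- sum(letterFrequency(assembly$seq, "N"))
  structure(list(total_length = sum(as.numeric(w)),
                 gap_length = as.numeric(gaps),
                 scaffold_n50 = n50(w),
                 scaffold_count = length(w)),
            class = "assembly_metrics")
}

#' Build assembly metrics from already-known numbers
#'
#' Used when the inputs are published summary values rather than sequences
#' (e.g. printed assembly-report tables).
#'
#' @param total_length,gap_length,scaffold_n50 values in bases
#' @param scaffold_count optional scaffold count
#' @return an `assembly_metrics` list
#' @export
assembly_metrics <- function(total_length, gap_length, scaffold_n50,
                             scaffold_count = NA_integer_) {
  stopifnot(gap_length >= 0, gap_length <= total_length, scaffold_n50 >= 0)
  structure(list(total_length = total_length, gap_length = gap_length,
                 scaffold_n50 = scaffold_n50, scaffold_count = scaffold_count),
            class = "assembly_metrics")
}

#' Display form of an N50 fold improvement
#'
#' Fold values of 10 or more are truncated to the integer part
#' (e.g. 130.94/0.10 = 1309.4 -> 1309, 133.38/0.17 = 784.6 -> 784); values
#' below 10 are rounded (half-to-even) to one decimal (145.94/38.75 = 3.766
#' -> 3.8), matching how assembly-improvement factors are conventionally
#' reported.
#'
#' @param fold positive ratio of N50 values
#' @return display value (numeric)
#' @export
format_fold <- function(fold) {
  stopifnot(fold > 0)
  if (fold >= 10) trunc(fold) else round(fold, 1L)
}

#' Compare a draft assembly with its chromosome-level successor
#'
#' @param draft,chrom `assembly_metrics` of the two assemblies (same species)
#' @return an `assembly_comparison` list: `n50_fold` (full precision),
#'   `n50_fold_display` (see [format_fold()]), `dn_abs` (gap-length change in
#'   bases, chromosome minus draft, signed), `dn_pct` (signed percent of the
#'   draft gap length; `NA` when the draft has no gaps) and
#'   `dn_pct_display` (rounded to integer percent)
#' @export
compare_assemblies <- function(draft, chrom) {
  stopifnot(inherits(draft, "assembly_metrics"),
            inherits(chrom, "assembly_metrics"))
  if (draft$scaffold_n50 <= 0) stopf("draft N50 must be positive")
  fold <- chrom$scaffold_n50 / draft$scaffold_n50
  dn_abs <- chrom$gap_length - draft$gap_length
  dn_pct <- if (draft$gap_length > 0) 100 * dn_abs / draft$gap_length else NA_real_
  structure(list(n50_fold = fold,
                 n50_fold_display = format_fold(fold),
                 dn_abs = dn_abs,
                 dn_pct = dn_pct,
                 dn_pct_display = if (is.na(dn_pct)) NA_real_ else round(dn_pct)),
            class = "assembly_comparison")
}

#' Write a two-assembly report in TSV form
#'
#' @param species species label
#' @param draft,chrom `assembly_metrics`
#' @param path output TSV path
#' @return the comparison (invisibly); side effect: writes `path` and a
#'   companion `<path>.comparison.tsv`
#' @export
write_assembly_report <- function(species, draft, chrom, path) {
  tab <- rbindlist(list(
    data.table(species = species, level = "draft",
               length_bp = draft$total_length, ns_bp = draft$gap_length,
               n50_bp = draft$scaffold_n50),
    data.table(species = species, level = "chr",
               length_bp = chrom$total_length, ns_bp = chrom$gap_length,
               n50_bp = chrom$scaffold_n50)))
  fwrite(tab, path, sep = "\t")
  cmp <- compare_assemblies(draft, chrom)
  fwrite(data.table(species = species,
                    n50_fold = cmp$n50_fold,
                    n50_fold_display = cmp$n50_fold_display,
                    dn_abs_bp = cmp$dn_abs,
                    dn_pct = cmp$dn_pct),
         paste0(tools::file_path_sans_ext(path), ".comparison.tsv"), sep = "\t")
  invisible(cmp)
}
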
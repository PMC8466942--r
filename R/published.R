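#' Path to a file shipped with the package
#' @param file file name under `extdata`
#' @return absolute path
#' @export
chromdiv_extdata <- function(file) {
  p <- system.file("extdata", file, package = "chromdiv")
  if (p == "") stopf("no such extdata file: %s", file)
  p
}

#' Published assembly summary statistics
#'
#' Printed draft and chromosome-level assembly-report values (genome length,
#' total gap length, scaffold N50) for eight mammal species with Hi-C
#' upgraded assemblies, as shipped in `extdata/published_assembly_stats.tsv`
#' (lengths in Gbp, gaps and N50 in Mbp).
#'
#' @return data.table with columns `species`, `level`, `length_gbp`,
#'   `ns_mbp`, `n50_mbp`
#' @export
published_assembly_stats <- function() {
  fread(chromdiv_extdata("published_assembly_stats.tsv"))
}

#' Published STR panel mapping counts
#'
#' Printed per-species counts of localized (L), not-amplified (NA) and
#' declined (D) markers from a 66-locus mustelid STR panel mapped onto six
#' chromosome-level assemblies, with chromosome counts, as shipped in
#' `extdata/published_str_counts.tsv`.
#'
#' @return data.table with columns `species`, `localized`, `not_amplified`,
#'   `declined`, `n_chromosomes`, `n_chrom_with_markers`
#' @export
published_str_counts <- function() {
  fread(chromdiv_extdata("published_str_counts.tsv"))
}

#' Plausible C-scaffold lengths for a mammalian genome
#'
#' Generates `n_chromosomes` lengths with a linearly decreasing size profile
#' (longest about three times the shortest, the usual shape of mammalian
#' karyotypes) scaled to a given total genome size. Used for window-count
#' arithmetic at genome scale without materializing sequence.
#'
#' @param total_length genome size in bases
#' @param n_chromosomes haploid chromosome number
#' @return numeric vector of scaffold lengths summing to ~`total_length`
#' @export
karyotype_lengths <- function(total_length, n_chromosomes) {
  w <- seq(3, 1, length.out = n_chromosomes)
  round(total_length * w / sum(w))
}
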
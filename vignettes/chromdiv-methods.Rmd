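---
title: "Methods and design notes for chromdiv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for chromdiv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`chromdiv` implements the analysis layer of a conservation-genomics workflow
built around chromosome-level (Hi-C scaffolded) genome assemblies of
non-model mammals. It starts *after* read alignment and variant calling: the
inputs are an assembly FASTA, a single-sample VCF annotated with per-sample
`DP`, `GQ` and `SP` FORMAT fields, a per-base read-depth track (bedGraph),
and an STR primer panel TSV. Read QC, alignment, mpileup calling,
whole-genome alignment to a karyotyped reference, and Zoo-FISH-based
chromosome assignment are out of scope.

# Models and procedures

## Assembly statistics

Scaffold N50 is the length `L` such that scaffolds of length >= `L` jointly
cover at least half of the assembly; when the cumulative sum hits exactly
50%, that scaffold's length is the N50 (the convention of common
assembly-stats tools). Gap length counts `N`/`n` bases only; other IUPAC
ambiguity codes are counted as sequence. For draft-versus-chromosome
comparisons the N50 fold improvement is reported at full precision plus a
display form: truncation to the integer for folds >= 10 and rounding to one
decimal below 10. The gap change dN is reported in bases (signed) and as a
signed percent of the draft gap length, displayed rounded to the nearest
integer; the rounding rule was chosen because it reproduces every published
display value we use as a reference target, including a case (sea otter,
-2.49% shown as -2%) that truncation toward zero would also satisfy but
plain rounding reproduces uniformly across all eight species.

## Variant filtering

A record is dropped iff `QUAL < 20 || SP > 60 || DP < 5 || GQ < 20`;
boundary values are kept. Records missing any required FORMAT value are
excluded with a warning and a tally — missing is surfaced as missing, never
as zero. The coverage-band rule retains bases whose depth lies within
50–250% of the whole-genome median; we take both ends as inclusive (the
source rule names the band without stating inclusivity; a symmetric closed
band is the testable choice). The mask is built from per-base depth. The
genome median is computed over the concatenation of all scaffolds, X
included. Mixed SNP/indel multi-allelic records go to the indel bucket:
downstream heterozygosity uses SNPs only, and short-read indel calls are
distrusted. Heterozygosity counts records whose genotype carries two
distinct allele indices; homozygous-alternative records are not
heterozygous.

## Heterozygosity windows

Heterozygous SNPs are counted in non-overlapping (stacking) windows of 100
kbp and 1 Mbp anchored at each scaffold start, scaled to SNPs per kbp.
Trailing partial windows are discarded rather than rescaled — this is what
makes 1-Mbp landscapes collapse on fragmented drafts (a draft with scaffold
N50 of 0.1 Mbp yields almost no complete 1-Mbp windows), which is the
phenomenon the window counts quantify. Gap content is not subtracted from
the window span; densities are per nominal window size. Windows never span
scaffolds.

## X chromosome and PAR detection

In a male, the X outside the pseudoautosomal region is hemizygous and
sequenced at ~0.5x of the autosomal depth, while the PAR (present on both X
and Y) stays at ~1x. The detector:

1. computes median depth in 10-kbp stacking windows along the candidate X
   (1-Mbp windows for the genome-wide scan), the trailing partial window
   using its actual bases;
2. labels windows by the ratio to the whole-genome median: *half* in
   [0.25, 0.75), *full* in [0.75, 1.25], *other* outside. The touching
   boundary at 0.75 is assigned to *full* (a tie rule is required; the
   published band limits touch);
3. identifies the X among chromosome-sized scaffolds (>= 10% of the longest
   scaffold's length by default) as the one with the largest fraction of
   half-band windows, requiring that fraction to exceed 0.5. Female samples
   are rejected: depth cannot distinguish the X from autosomes in a female,
   and the whole-genome-alignment route used in that situation is
   unsupported here;
4. detects the PAR in three stages on the 10-kbp medians: windows at
   >= 70% of the genome median are marked and adjacent marked windows
   merged into runs; only runs of >= 100 kbp survive; surviving runs are
   bridged into one region when the pooled median of the intervening
   windows' medians is itself >= 70% of the genome median.

The bridging criterion uses the *pooled* median of the gap windows rather
than requiring each gap window to pass individually — a per-window reading
would make the third stage redundant with the first. The 100-kbp retention
applies to merged run length, not to individual windows. The PAR is reported
wherever it is found; terminal position is observed, not enforced. A second
Y-linked PAR copy's effect on male depth normalization is ignored.

## Window-subset comparisons

Five subsets of 100-kbp windows are formed: `all`, `noX` (autosomes),
`onlyX`, `noPAR` (X minus PAR) and `PAR`. A window counts as PAR only when
its full span lies inside a PAR interval; boundary-straddling windows go to
`noPAR` so the small PAR sample is not diluted. The subset identities
`all = noX + onlyX` and `onlyX = noPAR + PAR` hold exactly and are asserted
in tests.

Two one-sided Mann–Whitney tests are run: "PAR is more heterozygous than
autosomes" (all individuals with a PAR call) and "autosomes are more
heterozygous than the hemizygous X" (females only — in a male the X body is
hemizygous and carries no heterozygous calls, making the second comparison
vacuous). Small samples (`min(n1, n2) <= 8` and `n1 + n2 <= 25`) use exact
enumeration over all rank assignments, which remains valid under ties;
larger samples use the tie-corrected normal approximation with continuity
correction. A 6-Mbp PAR yields only ~60 windows, hence the care with small
samples. When both samples are one constant value the test is degenerate
and returns p = 1 with a warning. Bonferroni correction uses the number of
tests actually run in the invocation as the family size — the source
analyses do not state their family size, and this choice is conservative
and reproducible.

## STR marker localization (in silico PCR)

Primer binding sites are end-to-end Hamming matches (no indels) on either
strand with at most 4 mismatches per primer; IUPAC codes in the primer match
their expansion sets, and an `N` in the genome matches nothing. 3'-end
mismatches are not weighted differently (plain counts). Two sites facing
each other on one scaffold within a 50–1000 bp outermost span form a
candidate amplicon; two-primer products are `FR`/`RF` by which primer is
upstream, and single-primer products (`FF`/`RR`) are emitted but flagged and
can never be localized — they do, however, move a marker from "no
amplification" to "declined".

Amplicons are ranked by a stable ascending sort on (MM, TM, length), where
MM = max(forward mismatches, reverse mismatches) and TM = their sum. The
published ranking sentence does not fix the key order between span length
and mismatch scores; mismatch-first is chosen here because the
classification rules are defined entirely on MM/TM separation. A marker is:

* `NA` — no amplicon at all;
* `L` group 1 — the top amplicon is FR/RF, MM <= 3, and it is the only one;
* `L` group 2 — top FR/RF with MM <= 3, and the second-ranked amplicon is
  separated by MM >= 2 or TM >= 3 ("adjacent amplicon" = second-ranked);
* `D` — everything else.

Per-chromosome reporting designates the `n` longest scaffolds as
C-scaffolds; localized markers landing on smaller scaffolds count as
unplaced. Marker density is reported both per chromosome and per
marker-bearing chromosome.

# The synthetic-data generator

The generator emulates the statistical structure the analysis assumes, so
every stage is testable offline: a multi-chromosome diploid genome with
spatially heterogeneous heterozygosity (per-autosome hotspot and a long
cold/homozygous stretch), an X with a terminal PAR, male X-body depth at
0.5x, VCF fields straddling each filter threshold, and primer scenarios
spanning the whole NA/D/L classification space (exact unique target; decoys
constructed on each side of the MM >= 2 / TM >= 3 separation boundaries; a
site at the MM = 4 allowance; a single-primer FF product; absent targets).

Default parameters (the stated world of the test-suite):

* genome: 4 autosomes x 2 Mbp + 2 Mbp X with a 300-kbp terminal PAR — a
  ~10-Mbp desk-scale genome that keeps chromosome:window and PAR:X
  proportions workable while a full pipeline run stays in minutes;
* heterozygosity rates (SNPs/kbp): autosome baseline 1.0, hotspot 2.0,
  coldspot 0.1, PAR 1.3, female X body 0.5, male X body 0 (hemizygous).
  Baseline ~1 SNP/kbp matches diverse mammals; 0.1 matches the "very low"
  band used in published heatmaps; PAR/autosome = 1.3 is a moderate planted
  elevation consistent with the reported PAR > autosome ordering;
* depth: 30x with per-base Poisson noise (negative binomial available as an
  overdispersion knob); Poisson is the simplest model that exercises the
  70% threshold and band classification;
* SNP placement by a thinned homogeneous Poisson process — exact, seedable,
  and matching the windowed-rate analysis assumptions;
* per-field filter-violation rate 5%, indel rate 5%, homozygous-alt rate 5%;
* draft fragmentation: scaffold lengths drawn exponentially so the scaffold
  N50 lands near the target (length-biased median of an exponential is
  ~1.678x its mean), one 100-bp N gap inserted per scaffold junction. The
  draft's non-N content equals the chromosome-level sequence exactly, so
  draft-vs-chromosome SNP-count equality can be asserted exactly.

What the generator does **not** emulate: read-level errors and mapping
artifacts, linkage/coalescent structure, GC-coverage bias, segmental
duplications, and real STR motif structure. A green test therefore
establishes the correctness of the implemented statistics and decision
rules on data satisfying their assumptions — not robustness to
misalignment or reference bias.

## A note on the large PAR simulation

The acceptance criterion for PAR detection uses 200 replicates with 4–8 Mbp
PARs on a 10-Mbp X at 20–60x depth. Drawing per-base Poisson depth for
~4.4 billion bases is not affordable on one CPU, but the detector consumes
only 10-kbp window medians and the genome-wide median. For a window of
`w` i.i.d. Poisson bases, the vector of counts of each depth value is
exactly Multinomial(`w`, Poisson pmf), and the window median is a
deterministic function of those counts; boundary windows use the
appropriate two-component mixture pmf. `simulate_depth_profile()` samples
window summaries from this exact law, so the 200-replicate study is
distributionally identical to per-base simulation at a tiny fraction of the
cost. The per-base route (`simulate_depth()`) is exercised end-to-end on
smaller genomes in the module tests and the pipeline test. The same
identical-law shortcut is used for the Mann–Whitney calibration study,
where window counts are Poisson draws at the planted rates — exactly the
distribution the placement process plus window counting induces.

# Numerical choices and degenerate inputs

* Median of an even-count multiset averages the two middle order statistics
  everywhere (depth tracks, window medians, genome median), consistent with
  `stats::median`.
* Empty coverage mask drops everything (with counts); a scaffold absent
  from the mask drops its records with a tally.
* Zero complete windows yields an `NA` summary with a warning rather than
  an error.
* `detect_par` returns an empty call with a warning when no run survives
  retention; `identify_x` fails loudly when no scaffold exceeds the 0.5
  half-band fraction.
* Heatmap color bins are left-closed: a density equal to a threshold lands
  in the upper bin. Default thresholds 0.1 and 0.75 SNPs/kbp follow the
  verbal bands used for published heatmaps and are user-overridable (the
  full published palette is not enumerated anywhere, so the defaults are a
  documented approximation).
* All generators are byte-deterministic under a fixed seed.

# Known limitations

* X identification requires a male sample; the female-only route (whole
  genome alignment to a karyotyped relative) is intentionally unsupported.
* The coverage mask is per-base; a windowed variant would be less noisy in
  half-coverage regions (in a male, roughly half the X body fails the 50%
  cutoff at typical depths because the per-base depth distribution
  straddles it).
* Exact Mann–Whitney enumeration is limited to small samples; beyond that
  the normal approximation's accuracy is relied upon (tie-free, its worst
  case against exact enumeration at n1 = n2 = 8 is ~0.0055 and shrinks with
  n; heavy ties at such small sizes can push the gap past 0.01, which is
  why small samples are routed to the exact test in the first place).
* Published per-species marker counts and window statistics from real data
  are not reproduced here — they require the original multi-GB read sets;
  the package reproduces the in-table arithmetic and the property-level
  behavior instead.
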
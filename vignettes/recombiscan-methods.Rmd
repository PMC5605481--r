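---
title: "Detecting somatic meiotic-like recombination from read-backed haplotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting somatic meiotic-like recombination from read-backed haplotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(recombiscan)
library(dplyr)
```

## The problem

Basidiomycete fungi such as the *Termitomyces* symbionts of fungus-growing
termites grow for most of their life as mycelium. When two compatible
homokaryons (mycelia carrying a single parental nuclear genotype) mate, the
resulting heterokaryon carries two genetically distinct nuclei per cell. If
those nuclei occasionally fuse and undergo a meiosis-like division during
vegetative growth, the footprint is homologous recombination between the two
parental genomes — detectable, genome-wide, from nothing more than short-read
sequencing of the mycelium.

`recombiscan` implements the read-backed detection procedure for this design:
a heterokaryon and its two parental homokaryons are sequenced (paired-end,
~250 bp reads, ~30–43× depth), aligned to a common draft reference, and the
aligned reads are scanned for *recombinant haplotypes*: reads whose alleles at
five consecutive heterozygous SNPs match neither of the two locally dominant
(parental) allele strings.

## The procedure

1. **Heterozygous SNP calling.** Pileups are built per sample, skipping
   alignments with mapping quality below 10 (MAPQ 10 itself is kept). A site
   is a heterozygous SNP when, with `c1 >= c2` the two largest A/C/G/T
   counts and `d` the MAPQ-passing depth, all of the following hold, every
   boundary inclusive:
   * `d >= 10`;
   * `(c1 + c2) / d >= 0.90`;
   * `(c1 - c2) / d <= 0.20`.
   The second allele must be seen at least once. The "difference" rule is
   interpreted as a fraction of total depth, matching how the 90% rule is
   phrased; both thresholds are configurable (`call_het_snps()`). Ties among
   counts break in base order A < C < G < T, so calls are deterministic.
2. **Cross-sample SNP filtering.** Heterozygous SNPs of the heterokaryon that
   are also detected in either homokaryon are discarded
   (`filter_shared_snps()`): a single-genotype mycelium should not be
   heterozygous, so such sites are suspected artifacts of duplicated or
   repetitive sequence rather than true inter-parental differences. Matching
   is by position; an allele-strict mode is available.
3. **Read-backed phasing.** Every read covering at least five heterozygous
   SNPs with a usable base (a called A/C/G/T equal to one of the site's two
   alleles) contributes one 5-character haplotype string over its first five
   phased sites (`extract_read_alleles()`, `build_windows()`). With two
   alleles per site a window admits `2^5 = 32` strings.
4. **Classification.** Within each window — keyed by its exact SNP position
   tuple — the two most frequent strings are the parental haplotypes; all
   other observed strings (at most 30) are recombinant (`classify_windows()`).
5. **Cross-sample haplotype filtering.** A heterokaryon recombinant string is
   excluded when either homokaryon shows the identical string as a recombinant
   in the identically positioned window (`filter_shared_recombinants()`);
   homokaryons can harbour intra-genome recombinants of their own (gene
   duplications, rearrangements), and anything they share with the
   heterokaryon cannot be attributed to inter-parental exchange. Excluded
   strings leave both the recombinant and the total counts.
6. **Summary and enrichment.** Per-sample read counts and percentages
   (rounded half-up to two decimals) are assembled into the four-column
   summary table (`summarize_sample()`, `make_table2()`), and recombinant
   reads are compared against a genic/intergenic partition of the genome:
   `fold = region's share of recombinant reads / region's share of genome bp`
   (`partition_genome()`, `enrichment()`).

On the real data this procedure reports roughly 19–20% recombinant phased
reads in the homokaryons, ~18.6% in the heterokaryon, and **5.04%** after the
cross-sample haplotype filter — the headline estimate of somatic meiotic-like
recombination.

## Parameters that matter

| parameter | default | unit | role |
|---|---|---|---|
| `mapq_min` | 10 | MAPQ | alignments below it contribute nothing |
| `min_depth` | 10 | reads | minimum MAPQ-passing depth at a SNP |
| `major_frac` | 0.90 | fraction | minimum combined share of the top two alleles |
| `max_diff` | 0.20 | fraction | maximum top-two count difference over depth |
| `k` | 5 | SNPs | haplotype window size |
| `window_policy` | `"leading"` | — | one window per read vs all sliding windows |

The `"leading"` policy gives each phased read exactly one haplotype string,
which keeps the summary's read counts additive (each read counted once). The
`"sliding"` alternative classifies a read recombinant if *any* of its windows
does; it is more sensitive to crossovers near read ends but no longer maps
one-to-one onto window counts, so summaries then work from per-read labels
(`label_reads()`).

Mates of a pair are treated as independent reads throughout — the procedure
counts reads, and no mate-merging step is defined. A read base matching
neither called allele is treated as a sequencing error and that site is
dropped from the read's vector (`unusable = "drop_site"`); the strict mode
discards the read instead.

## What the simulator emulates

`simulate_trio()` generates the full study design with ground truth:

* a random reference (default one 100 kb scaffold; tests and the acceptance
  script use 50–200 kb, chosen so a full run stays in seconds while still
  containing dozens of SNP clusters), partitioned into genes of 1 kb so the
  genic share is exact to one gene's granularity;
* two parental haplotypes differing at a Binomial(L, `snp_rate`) number of
  sites (default 1 per kb, the density seen in this system);
* **clustered SNP placement**: positions are grouped into clusters of about
  `snp_cluster_size = 6` sites, 2–15 bp apart. This mirrors the locally dense
  heterozygosity of highly variable fungal genomes (the worked real-data
  window spans five SNPs within 18 bp) and is what makes 5-SNP phasing by a
  250 bp read possible at all: under uniform placement at 1 SNP/kb a read
  would cover five SNPs with probability ~`1e-7` and the method would have
  nothing to phase;
* a molecule pool per scaffold in which a fraction `recomb_fraction` carries a
  single crossover, the interval drawn uniformly among inter-SNP intervals
  and the breakpoint uniformly inside it (recorded at half-integer
  coordinates, hence strictly between the flanking SNPs); the remainder
  splits between the parentals (evenly for the heterokaryon; single-parental
  for the homokaryons);
* reads drawn in pairs from molecules to the target depth, with substitution
  errors at `error_rate` and a stated fraction of MAPQ-below-10 reads;
  parental haplotype 1 *is* the reference, so simulated alignments are exact
  and the pipeline is decoupled from any external aligner;
* `make_crossover(..., reciprocal = TRUE)` injects both products of a stated
  exchange into any sample's pool. Reciprocal injection matters: a large
  one-sided injection shifts per-site allele balance beyond the 20% rule and
  silently suppresses SNP calls, whereas the reciprocal pair is balance-neutral
  (and is what a real exchange produces).

The simulator does **not** model indels, base-quality-dependent errors, PCR
duplicates, insert-size distributions, GC bias, mapping ambiguity in repeats,
or reference bias. Passing tests therefore demonstrate the *logic* of the
procedure — thresholds, phasing, classification, filtering, arithmetic — not
robustness to real-data artifacts such as mismapping in duplicated regions,
which is exactly the failure mode the two cross-sample filters exist to
absorb.

## Numerical and design choices

* **Inclusive thresholds with a tolerance.** `(c1 + c2) >= 0.90 * d` is
  evaluated with a `1e-9` slack so that exact boundary cases (9 of 10 reads)
  are not lost to binary floating-point representation.
* **Rounding.** Percentages round half away from zero to two decimals
  (`5.125 -> 5.13`), matching the published table's formatting, rather than
  R's banker's rounding.
* **Ties.** Equal counts at the parental cut break lexicographically; a
  single observed string is parental with no recombinants; zero phased reads
  yield `NA` percentages rather than an error.
* **Window keys.** Windows are compared across samples by exact
  (scaffold, 5-position) tuples. Because each sample calls its own SNPs, and
  balanced sites near the 20%-difference boundary drop out stochastically at
  ~35× depth, per-sample site sets differ; heterokaryon windows with no
  same-positioned homokaryon window are conservatively retained. The
  `common_window_sites` option of `run_scan()` genotypes every sample at the
  heterokaryon's sites instead, making keys directly comparable.
* **Order of the two filters.** The published pipeline filters shared SNPs
  *before* haplotype inference. Taken literally, that removes every
  heterokaryon site at which a homokaryon is also heterozygous — the very
  sites where identically keyed windows could exist — so the window-level
  shared-haplotype filter mostly acts on windows that survive because the
  homokaryon site set differed. `run_scan()` keeps both stages and exposes
  `filter_shared_snps` as a toggle for studying scenarios (e.g. a duplicated
  region carrying both haplotypes) where the window-level filter must act.
* **Read-to-region assignment** uses the alignment midpoint by default; a
  base-pair-overlap weighting is available. Region vocabulary is
  genic/intergenic, extended to exon/intron only when the annotation carries
  exon features.
* **Expected recombinant fraction on simulated data.** A read is expected
  recombinant exactly when its source molecule's breakpoint falls strictly
  inside its window span. At realistic error rates a second term matters: an
  error at one of the window's `k` sites converts to the site's *other*
  allele with probability 1/3, turning a parental read into a recombinant
  string, so parental reads misclassify at
  `p_flip = 1 - (1 - error_rate/3)^k` (~0.17% at `1e-3`). At the study's
  scale the truth signal within a window (a window spans 4 of ~200 inter-SNP
  intervals) and this error floor are of the same order — a fraction of a
  percent — so `expected_recombinant_fraction()` combines both terms, each
  derived from the generative model rather than from pipeline output, and the
  recovery tests compare observed fractions against that expectation within
  three binomial standard deviations. The same error floor is why a null
  simulation (no recombinant molecules, `error_rate = 1e-3`) still shows up
  to ~0.5% recombinant calls, and why sequencing errors can only inflate the
  estimate, never deflate it.

## A worked run

```{r worked, eval = FALSE}
cfg <- sim_config(scaffold_length = 100000, mean_depth = 35,
                  recomb_fraction = 0.05, seed = 1)
trio <- simulate_trio(cfg)
lens <- setNames(nchar(trio$reference$sequences),
                 names(trio$reference$sequences))
scan <- run_scan(trio$samples$heterokaryon$reads,
                 trio$samples$homokaryon1$reads,
                 trio$samples$homokaryon2$reads,
                 scaffold_lengths = lens,
                 annotation = trio$reference$genes)
scan$table2
glance(scan)
autoplot(scan)
autoplot(scan$enrichment)
```

## Known limitations

* Only biallelic SNPs are used; indels and multi-allelic sites are out of
  scope, as are genotype likelihoods and base-quality recalibration.
* No statistical phasing across windows is attempted — parental designation
  is local to each 5-SNP window, so globally phased parental chromosomes are
  never reconstructed.
* Breakpoints are not fine-mapped; a recombinant call localises a crossover
  only to within a window span.
* The recombinant *read* fraction is not a recombination *rate* per genome:
  it confounds crossover density, SNP clustering, depth, and window
  geometry. Comparisons are meaningful between samples sequenced and
  processed identically — which is exactly how the four-column summary table
  is used.
* The simulator's single-crossover molecules cannot represent gene
  conversion or double crossovers within one window; both would appear simply
  as "recombinant".

## Reproducing the real-data analysis

The original inputs (SRA study SRP073090 and the *Termitomyces* sp. J132
reference with its annotation) are multi-gigabyte and need hours of external
alignment, so they are not part of the test suite. The installed recipe —
`srp073090_recipe_path()` — documents the download, alignment (Bowtie 2,
local mode, after adapter trimming) and the exact `run_scan()` call, with the
published 5.04% filtered recombinant fraction as the expected outcome.
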
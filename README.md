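# recombiscan

Read-backed detection of **somatic meiotic-like recombination** in fungal
heterokaryons from short-read sequencing.

## The problem

When two compatible fungal homokaryons (mycelia carrying a single parental
nuclear genotype) mate, the heterokaryon carries two distinct nuclei per
cell. If those nuclei occasionally fuse and divide meiotically during
ordinary hyphal growth, the two parental genomes recombine — and the
footprint is visible in whole-genome short reads of the mycelium as
*recombinant haplotypes*: reads whose alleles at several nearby heterozygous
SNPs match neither locally dominant allele string. `recombiscan` implements
the full detection pipeline for the three-sample design (heterokaryon + its
two parental homokaryons aligned to a shared reference), plus a seeded
synthetic-data generator with complete ground truth so every stage is
testable without any downloads.

## The method

For each sample, with `c1 >= c2` the two largest base counts at a site and
`d` the depth from alignments with MAPQ >= 10, a **heterozygous SNP**
requires (all boundaries inclusive):

    d >= 10,   (c1 + c2)/d >= 0.90,   (c1 - c2)/d <= 0.20

Heterokaryon SNPs also detected in either homokaryon are discarded. Every
read phased at **>= 5 heterozygous SNPs** contributes a 5-character haplotype
string over its first five phased sites; within each window (keyed by its
exact SNP positions) the **two most frequent strings are parental**, and the
up-to-30 other observed strings (of the `2^5 = 32` possible) are
**recombinant**. Recombinant strings that either homokaryon also shows in the
identically keyed window are excluded — a homokaryon cannot undergo
inter-parental exchange, so whatever it shares is an intra-genome artifact.
Finally, recombinant reads are compared against a genic/intergenic partition
of the genome:

    fold_enrichment(region) = (% of recombinant reads in region) / (% of genome in region)

## A worked example

```r
library(recombiscan)

# simulate a heterokaryon + two homokaryons: 100 kb reference, ~1 het SNP/kb
# (locally clustered), 250 bp reads at 35x, 30% of heterokaryon molecules
# carrying one crossover (exaggerated so the example shows recombinants)
cfg  <- sim_config(scaffold_length = 100000, mean_depth = 35,
                   recomb_fraction = 0.3, seed = 1)
trio <- simulate_trio(cfg)
lens <- setNames(nchar(trio$reference$sequences),
                 names(trio$reference$sequences))

scan <- run_scan(trio$samples$heterokaryon$reads,
                 trio$samples$homokaryon1$reads,
                 trio$samples$homokaryon2$reads,
                 scaffold_lengths = lens,
                 annotation = trio$reference$genes)
tidy(scan)
glance(scan)
```

which prints

```
                  label nonrecombinant_reads recombinant_reads total_reads nonrecombinant_pct recombinant_pct
1           homokaryon1                    0                 0           0                 NA              NA
2           homokaryon2                    0                 0           0                 NA              NA
3          heterokaryon                  403                 8         411              98.05            1.95
4 filtered_heterokaryon                  403                 8         411              98.05            1.95

  het_snps_raw het_snps_used phased_reads recombinant_reads recombinant_pct excluded_shared_haplotypes genic_fold_enrichment
1           78            78          411                 8            1.95                          0                0.9375
```

Reading it: the heterokaryon yields 78 heterozygous SNPs (none shared with
the homokaryons, which are single-genotype and so call no SNPs at all); 411
reads are phased at five or more of them; 8 of those (1.95%) carry a window
haplotype other than the two parental strings — the recombinants. None are
shared with a homokaryon, so the filtered column is unchanged. The
recombinant reads sit near-uniformly over the genic (40%) and intergenic
(60%) partition:

```
scan$enrichment
      region genome_bp genome_pct recombinant_count recombinant_pct fold_enrichment
1 intergenic     60000         60                 5            62.5        1.041667
2      genic     40000         40                 3            37.5        0.937500
```

`autoplot(scan)` and `autoplot(scan$enrichment)` draw the per-sample stacked
percentages and the fold-enrichment bars. `write_report(scan, "report.json")`
serialises counts, thresholds and checksums. Individual stages are exported
(`build_pileup()`, `call_het_snps()`, `filter_shared_snps()`,
`extract_read_alleles()`, `build_windows()`, `classify_windows()`,
`filter_shared_recombinants()`, `summarize_sample()`, `make_table2()`,
`partition_genome()`, `enrichment()`), all taking and returning tibbles so
they compose with the pipe. A thin command-line wrapper lives at
`inst/cli/recombiscan.R` (`simulate`, `callsnps`, `run`).

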
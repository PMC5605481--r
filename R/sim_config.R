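#' Configuration for the synthetic heterokaryon read simulator
#'
#' Bundles every tunable of the synthetic-data generator and validates it.
#' Defaults emulate the sequencing design the pipeline was built for:
#' paired-end 250 bp reads at ~35x depth over a draft fungal genome carrying
#' roughly one heterozygous SNP per kilobase, with the SNPs locally clustered
#' (a handful of sites within a few tens of bases) as observed in highly
#' variable fungal genomes -- without clustering a 250 bp read would almost
#' never span the five heterozygous SNPs that read-backed phasing requires.
#'
#' @param n_scaffolds Number of reference scaffolds.
#' @param scaffold_length Length of each scaffold in bp; must be at least
#'   `read_length`.
#' @param snp_rate Expected heterozygous SNPs per bp. The per-scaffold SNP
#'   count is Binomial(`scaffold_length`, `snp_rate`); positions are placed in
#'   clusters (see `snp_cluster_size`). Default `1e-3` (~1/kb).
#' @param recomb_fraction Fraction of source molecules that carry a single
#'   crossover between the two parental haplotypes, in `[0, 1]`.
#' @param read_length Read length in bp (default 250, i.e. 250 sequencing
#'   cycles).
#' @param mean_depth Expected fold coverage (default 35, matching the ~32-43x
#'   range of the motivating libraries).
#' @param error_rate Per-base substitution error probability.
#' @param seed Integer RNG seed; every simulator stage derives its stream from
#'   it, so identical configs give byte-identical outputs.
#' @param genic_fraction Fraction of each scaffold annotated as genic, in
#'   `[0, 1]`.
#' @param snp_cluster_size Target number of SNPs per cluster (default 6; use 1
#'   for near-uniform placement).
#' @param snp_cluster_spacing Integer range (length 2) of gaps in bp between
#'   neighbouring SNPs inside a cluster.
#' @param n_molecules Source molecules simulated per scaffold; reads sample
#'   molecules uniformly.
#' @param low_mapq_fraction Fraction of reads assigned a mapping quality below
#'   10 (drawn uniformly from 0-9) to exercise the MAPQ filter.
#' @param mapq_high MAPQ assigned to the remaining reads.
#' @param gene_length Length in bp of each simulated gene interval.
#'
#' @return A validated list of class `sim_config`.
#' @examples
#' cfg <- sim_config(scaffold_length = 50000, seed = 7)
#' cfg$snp_rate
#' @export
sim_config <- function(n_scaffolds = 1L,
                       scaffold_length = 100000L,
                       snp_rate = 1e-3,
                       recomb_fraction = 0.05,
                       read_length = 250L,
                       mean_depth = 35,
                       error_rate = 0.001,
                       seed = 1L,
                       genic_fraction = 0.4,
                       snp_cluster_size = 6L,
                       snp_cluster_spacing = c(2L, 15L),
                       n_molecules = 2000L,
                       low_mapq_fraction = 0.05,
                       mapq_high = 60L,
                       gene_length = 1000L) {
  cfg <- list(
    n_scaffolds = as.integer(n_scaffolds),
    scaffold_length = as.integer(scaffold_length),
    snp_rate = snp_rate,
    recomb_fraction = recomb_fraction,
    read_length = as.integer(read_length),
    mean_depth = mean_depth,
    error_rate = error_rate,
    seed = as.integer(seed),
    genic_fraction = genic_fraction,
    snp_cluster_size = as.integer(snp_cluster_size),
    snp_cluster_spacing = as.integer(snp_cluster_spacing),
    n_molecules = as.integer(n_molecules),
    low_mapq_fraction = low_mapq_fraction,
    mapq_high = as.integer(mapq_high),
    gene_length = as.integer(gene_length)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  chk_count <- function(field, min = 1L) {
    v <- cfg[[field]]
    if (length(v) != 1L || is.na(v) || v < min) {
      stop_field(field, sprintf("must be a single integer >= %d", min))
    }
  }
  chk_rate <- function(field) {
    v <- cfg[[field]]
    if (length(v) != 1L || is.na(v) || v < 0 || v > 1) {
      stop_field(field, "must be a single value in [0, 1]")
    }
  }
  chk_count("n_scaffolds")
  chk_count("scaffold_length")
  chk_count("read_length")
  chk_count("n_molecules")
  chk_count("gene_length")
  chk_count("snp_cluster_size")
  chk_count("seed", min = 0L)
  for (f in c("snp_rate", "recomb_fraction", "error_rate",
              "genic_fraction", "low_mapq_fraction")) {
    chk_rate(f)
  }
  if (length(cfg$mean_depth) != 1L || is.na(cfg$mean_depth) || cfg$mean_depth <= 0) {
    stop_field("mean_depth", "must be a single positive number")
  }
  if (cfg$scaffold_length < cfg$read_length) {
    stop_field("scaffold_length", sprintf(
      "must be >= read_length (%d); got %d", cfg$read_length, cfg$scaffold_length
    ))
  }
  if (cfg$snp_rate > 0 && cfg$snp_rate * cfg$scaffold_length < 5) {
    stop_field("snp_rate", sprintf(
      "snp_rate * scaffold_length = %.2f < 5; five-SNP phasing windows would be impossible",
      cfg$snp_rate * cfg$scaffold_length
    ))
  }
  if (length(cfg$snp_cluster_spacing) != 2L ||
      any(cfg$snp_cluster_spacing < 1L) ||
      cfg$snp_cluster_spacing[1] > cfg$snp_cluster_spacing[2]) {
    stop_field("snp_cluster_spacing", "must be an increasing pair of gaps >= 1 bp")
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  genome: %d scaffold(s) x %d bp, genic fraction %.2f\n",
              x$n_scaffolds, x$scaffold_length, x$genic_fraction))
  cat(sprintf("  SNPs: rate %.2g/bp, clusters of ~%d (gaps %d-%d bp)\n",
              x$snp_rate, x$snp_cluster_size,
              x$snp_cluster_spacing[1], x$snp_cluster_spacing[2]))
  cat(sprintf("  molecules: %d per scaffold, recombinant fraction %.3f\n",
              x$n_molecules, x$recomb_fraction))
  cat(sprintf("  reads: %d bp, depth %.1fx, error rate %.2g, MAPQ<10 fraction %.2f\n",
              x$read_length, x$mean_depth, x$error_rate, x$low_mapq_fraction))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

# deterministic per-stage sub-seed; keeps all seeds well below 2^31
stage_seed <- function(cfg, stage) {
  offsets <- c(reference = 1L, haplotypes = 2L, pool = 3L, reads = 4L)
  if (!stage %in% names(offsets)) abort(paste0("unknown simulator stage: ", stage))
  (cfg$seed %% 20000000L) * 100L + offsets[[stage]]
}
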
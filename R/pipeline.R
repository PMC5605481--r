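#' Run the full recombination scan on a heterokaryon and its two homokaryons
#'
#' Orchestrates the whole pipeline: MAPQ-filtered pileups and heterozygous SNP
#' calls per sample; removal of heterokaryon SNPs also detected in either
#' homokaryon (optional); read-backed phasing into k-SNP haplotype windows;
#' parental/recombinant classification per window; removal of heterokaryon
#' recombinant haplotypes shared with a homokaryon; the four-sample summary
#' table; and, when an annotation is given, fold enrichment of the filtered
#' heterokaryon's recombinant reads over genic/intergenic regions.
#'
#' @param heterokaryon,homokaryon1,homokaryon2 Alignment tibbles (`read_id`,
#'   `scaffold`, `pos`, `seq`, `mapq`) or BAM/SAM paths.
#' @param scaffold_lengths Named integer vector of scaffold lengths (required
#'   when `annotation` is given).
#' @param annotation Optional gene annotation (tibble or GFF3 path) for the
#'   enrichment stage.
#' @param mapq_min,min_depth,major_frac,max_diff Heterozygous SNP calling
#'   thresholds; see [call_het_snps()]. All boundaries inclusive.
#' @param k,window_policy Haplotype window size and policy; see
#'   [build_windows()].
#' @param filter_shared_snps Drop heterokaryon SNPs also called in a
#'   homokaryon before phasing (default `TRUE`). Disable to study scenarios
#'   where a homokaryon is deliberately heterozygous at the same sites, e.g. a
#'   duplicated region, so the window-level shared-recombinant filter can act.
#' @param common_window_sites Build every sample's haplotype windows at the
#'   heterokaryon's heterozygous sites instead of each sample's own calls
#'   (default `FALSE`). Windows are compared across samples by their exact
#'   SNP-position tuple, and sampling noise at the allele-balance thresholds
#'   makes per-sample site sets differ; genotyping all samples at a common
#'   site set makes the shared-recombinant filter's window keys comparable.
#' @return An object of class `recombiscan_scan`: a list with `snps` (per
#'   sample, plus `heterokaryon_raw`), `windows` (classified, per sample, plus
#'   `heterokaryon_filtered`), `excluded_haplotypes`, `summaries` (4-row
#'   tibble), `table2`, `enrichment` (or `NULL`), `params` and `counts`.
#' @examples
#' trio <- simulate_trio(sim_config(scaffold_length = 20000, mean_depth = 20,
#'                                  seed = 5))
#' scan <- run_scan(trio$samples$heterokaryon$reads,
#'                  trio$samples$homokaryon1$reads,
#'                  trio$samples$homokaryon2$reads)
#' glance(scan)
#' @export
run_scan <- function(heterokaryon, homokaryon1, homokaryon2,
                     scaffold_lengths = NULL, annotation = NULL,
                     mapq_min = 10L, min_depth = 10L, major_frac = 0.90,
                     max_diff = 0.20, k = 5L,
                     window_policy = c("leading", "sliding"),
                     filter_shared_snps = TRUE, common_window_sites = FALSE) {
  window_policy <- match.arg(window_policy)
  params <- list(mapq_min = mapq_min, min_depth = min_depth,
                 major_frac = major_frac, max_diff = max_diff, k = k,
                 window_policy = window_policy,
                 filter_shared_snps = filter_shared_snps,
                 common_window_sites = common_window_sites)
  load_aln <- function(x, stage) {
    tryCatch({
      if (is.character(x)) read_alignments(x) else as_tibble(x)
    }, error = function(e) {
      abort(sprintf("stage load_alignments (%s) failed: %s", stage,
                    conditionMessage(e)))
    })
  }
  aln <- list(
    heterokaryon = load_aln(heterokaryon, "heterokaryon"),
    homokaryon1 = load_aln(homokaryon1, "homokaryon1"),
    homokaryon2 = load_aln(homokaryon2, "homokaryon2")
  )

  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("stage %s failed: %s", stage, conditionMessage(e)))
    })
  }

  snps <- run_stage("call_het_snps", {
    map(aln, function(a) {
      call_het_snps(build_pileup(a, mapq_min = mapq_min),
                    min_depth = min_depth, major_frac = major_frac,
                    max_diff = max_diff)
    })
  })
  snps$heterokaryon_raw <- snps$heterokaryon
  if (filter_shared_snps) {
    snps$heterokaryon <- run_stage("filter_shared_snps", {
      filter_shared_snps(snps$heterokaryon_raw, snps$homokaryon1,
                         snps$homokaryon2)
    })
  }

  windows <- run_stage("haplotype_windows", {
    purrr::imap(aln, function(a, nm) {
      sites <- if (common_window_sites) snps$heterokaryon else snps[[nm]]
      ra <- extract_read_alleles(a, sites, mapq_min = mapq_min)
      classify_windows(build_windows(ra, k = k, policy = window_policy))
    })
  })
  windows$heterokaryon_filtered <- run_stage("filter_shared_recombinants", {
    filter_shared_recombinants(windows$heterokaryon, windows$homokaryon1,
                               windows$homokaryon2)
  })
  excluded <- attr(windows$heterokaryon_filtered, "excluded")

  summaries <- run_stage("summarize", {
    bind_rows(
      summarize_sample(windows$homokaryon1, "homokaryon1"),
      summarize_sample(windows$homokaryon2, "homokaryon2"),
      summarize_sample(windows$heterokaryon, "heterokaryon"),
      summarize_sample(windows$heterokaryon_filtered, "filtered_heterokaryon")
    )
  })
  table2 <- run_stage("make_table2", make_table2(summaries))

  enrich <- NULL
  if (!is.null(annotation)) {
    if (is.null(scaffold_lengths)) {
      abort("stage enrichment failed: `scaffold_lengths` is required with `annotation`")
    }
    enrich <- run_stage("enrichment", {
      part <- partition_genome(annotation, scaffold_lengths)
      rec <- label_reads(
        # reads whose (window, string) survived filtering and are recombinant
        extract_read_alleles(aln$heterokaryon, snps$heterokaryon,
                             mapq_min = mapq_min) |>
          build_windows(k = k, policy = window_policy),
        windows$heterokaryon_filtered
      )
      rec <- rec[rec$class == "recombinant", ]
      rec_aln <- aln$heterokaryon[aln$heterokaryon$read_id %in% rec$read_id, ]
      if (nrow(rec_aln) == 0L) NULL else enrichment(rec_aln, part)
    })
  }

  counts <- list(
    reads = map_int(aln, nrow),
    het_snps_raw = map_int(snps[c("heterokaryon_raw", "homokaryon1",
                                  "homokaryon2")], nrow),
    het_snps_used = nrow(snps$heterokaryon),
    excluded_shared_haplotypes = nrow(excluded %||% tibble())
  )

  structure(
    list(snps = snps, windows = windows, excluded_haplotypes = excluded,
         summaries = summaries, table2 = table2, enrichment = enrich,
         params = params, counts = counts),
    class = "recombiscan_scan"
  )
}

#' @export
print.recombiscan_scan <- function(x, ...) {
  cat("<recombiscan_scan>\n")
  cat(sprintf("  thresholds: MAPQ>=%d, depth>=%d, top2>=%.0f%%, diff<=%.0f%%, k=%d (%s windows)\n",
              x$params$mapq_min, x$params$min_depth, 100 * x$params$major_frac,
              100 * x$params$max_diff, x$params$k, x$params$window_policy))
  cat(sprintf("  heterozygous SNPs: %d raw -> %d used (heterokaryon)\n",
              x$counts$het_snps_raw[["heterokaryon_raw"]], x$counts$het_snps_used))
  cat(sprintf("  shared recombinant haplotypes excluded: %d\n",
              x$counts$excluded_shared_haplotypes))
  print(x$table2)
  invisible(x)
}

#' Tidy the per-sample summary of a recombination scan
#'
#' @param x A `recombiscan_scan` object.
#' @param ... Unused.
#' @return The 4-row per-sample summary tibble (label, read counts,
#'   percentages).
#' @method tidy recombiscan_scan
#' @export
tidy.recombiscan_scan <- function(x, ...) {
  x$summaries
}

#' One-row overview of a recombination scan
#'
#' @param x A `recombiscan_scan` object.
#' @param ... Unused.
#' @return One-row tibble: SNP counts, phased read counts, the filtered
#'   heterokaryon recombinant percentage, number of excluded shared
#'   haplotypes, and (when computed) genic fold enrichment.
#' @method glance recombiscan_scan
#' @export
glance.recombiscan_scan <- function(x, ...) {
  filt <- x$summaries[x$summaries$label == "filtered_heterokaryon", ]
  genic_fold <- NA_real_
  if (!is.null(x$enrichment)) {
    g <- x$enrichment$fold_enrichment[x$enrichment$region %in% c("genic", "exon")]
    if (length(g) > 0) genic_fold <- g[1]
  }
  tibble(
    het_snps_raw = x$counts$het_snps_raw[["heterokaryon_raw"]],
    het_snps_used = x$counts$het_snps_used,
    phased_reads = filt$total_reads,
    recombinant_reads = filt$recombinant_reads,
    recombinant_pct = filt$recombinant_pct,
    excluded_shared_haplotypes = x$counts$excluded_shared_haplotypes,
    genic_fold_enrichment = genic_fold
  )
}

#' @describeIn run_scan Stacked per-sample percentage bars of parental vs
#'   recombinant phased reads.
#' @param object A `recombiscan_scan` object.
#' @method autoplot recombiscan_scan
#' @export
autoplot.recombiscan_scan <- function(object, ...) {
  long <- object$summaries |>
    select("label", "nonrecombinant_pct", "recombinant_pct") |>
    pivot_longer(-"label", names_to = "class", values_to = "pct") |>
    mutate(class = ifelse(.data$class == "recombinant_pct",
                          "recombinant", "non-recombinant"),
           label = factor(.data$label, levels = object$summaries$label))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$label, y = .data$pct,
                                     fill = .data$class)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "phased reads (%)",
                  title = "Parental vs recombinant haplotypes per sample") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 20, hjust = 1))
}

#' Write a machine-readable report of a recombination scan
#'
#' Serialises all counts, percentages, thresholds, the package version, and
#' (for file inputs) MD5 checksums to JSON, so a run is fully auditable and
#' reproducible.
#'
#' @param scan A `recombiscan_scan` object.
#' @param path Output JSON path.
#' @param inputs Optional named character vector of input file paths to
#'   checksum.
#' @return `path`, invisibly.
#' @export
write_report <- function(scan, path, inputs = NULL) {
  report <- list(
    tool = "recombiscan",
    version = as.character(packageVersion("recombiscan")),
    params = scan$params,
    counts = scan$counts,
    summaries = scan$summaries,
    table2 = as.data.frame(scan$table2),
    enrichment = if (is.null(scan$enrichment)) NULL else
      as.data.frame(scan$enrichment),
    input_md5 = if (is.null(inputs)) NULL else
      as.list(tools::md5sum(inputs))
  )
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
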
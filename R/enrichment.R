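#' Partition the genome into labeled regions
#'
#' Assigns every base pair of every scaffold exactly one region label. Gene
#' intervals (unioned, so overlapping genes are not double-counted) are
#' `genic`; everything else is `intergenic`. When the annotation carries
#' `exon` features, genic bases are split into `exon` (any exon overlap wins)
#' and `intron`.
#'
#' @param annotation Gene annotation: a tibble with `scaffold`, `start`, `end`
#'   (1-based closed) and optionally `type`, or a GFF3 path, or `NULL` for no
#'   annotation (everything intergenic).
#' @param scaffold_lengths Named integer vector of scaffold lengths.
#' @return Partition tibble: `scaffold`, `start`, `end`, `region`; intervals
#'   are disjoint and cover each scaffold completely.
#' @examples
#' genes <- tibble::tibble(scaffold = "s", start = 1L, end = 400L)
#' partition_genome(genes, c(s = 1000L)) # genic 40%, intergenic 60%
#' @export
partition_genome <- function(annotation, scaffold_lengths) {
  if (is.character(annotation) && length(annotation) == 1L) {
    annotation <- read_gff3(annotation)
  }
  if (is.null(annotation) || nrow(annotation) == 0L) {
    annotation <- tibble(scaffold = character(), start = integer(),
                         end = integer())
  }
  bad <- annotation$scaffold[!annotation$scaffold %in% names(scaffold_lengths) |
                               annotation$start < 1L |
                               annotation$end > scaffold_lengths[annotation$scaffold]]
  if (length(bad) > 0L) {
    i <- which(!annotation$scaffold %in% names(scaffold_lengths) |
                 annotation$start < 1L |
                 annotation$end > scaffold_lengths[annotation$scaffold])[1]
    abort(sprintf("annotation interval out of scaffold bounds: %s:%d-%d",
                  annotation$scaffold[i], annotation$start[i], annotation$end[i]))
  }
  has_type <- "type" %in% names(annotation)
  use_exons <- has_type && any(annotation$type == "exon")
  gene_rows <- if (has_type) {
    annotation[annotation$type %in% c("gene", "exon", "intron"), ]
  } else {
    annotation
  }
  map(names(scaffold_lengths), function(s) {
    L <- scaffold_lengths[[s]]
    full <- IRanges::IRanges(1L, L)
    g <- gene_rows[gene_rows$scaffold == s, ]
    genic <- IRanges::reduce(IRanges::IRanges(g$start, g$end))
    intergenic <- IRanges::setdiff(full, genic)
    pieces <- list()
    if (use_exons) {
      e <- annotation[annotation$scaffold == s & annotation$type == "exon", ]
      exon <- IRanges::intersect(
        IRanges::reduce(IRanges::IRanges(e$start, e$end)), genic)
      intron <- IRanges::setdiff(genic, exon)
      pieces$exon <- exon
      pieces$intron <- intron
    } else {
      pieces$genic <- genic
    }
    pieces$intergenic <- intergenic
    purrr::imap(pieces, function(ir, nm) {
      tibble(scaffold = s, start = IRanges::start(ir), end = IRanges::end(ir),
             region = nm)
    }) |> list_rbind()
  }) |> list_rbind() |> arrange(.data$scaffold, .data$start)
}

#' Fold enrichment of recombinant reads over genomic regions
#'
#' Assigns each recombinant read to one region (by default the region under
#' its alignment midpoint; optionally by fractional base-pair overlap) and
#' compares the region's share of recombinant reads against its share of the
#' genome: `fold = recombinant_pct / genome_pct`. A fold above 1 means
#' recombinants are enriched in that region, below 1 depleted; when all reads
#' fall inside the partition the genome-share-weighted mean fold is exactly 1.
#'
#' @param reads Tibble of recombinant reads with `scaffold`, `pos` and either
#'   `width` or `seq`.
#' @param partition Partition tibble from [partition_genome()].
#' @param weight `"midpoint"` (default) assigns each read to the region under
#'   its alignment midpoint; `"overlap"` spreads each read over regions in
#'   proportion to overlapping base pairs.
#' @return Region tibble of class `recombiscan_regions`: `region`,
#'   `genome_bp`, `genome_pct`, `recombinant_count`, `recombinant_pct`,
#'   `fold_enrichment`.
#' @export
enrichment <- function(reads, partition, weight = c("midpoint", "overlap")) {
  weight <- match.arg(weight)
  widths <- if ("width" %in% names(reads)) reads$width else nchar(reads$seq)
  region_levels <- unique(partition$region)
  genome <- partition |>
    mutate(bp = .data$end - .data$start + 1) |>
    group_by(.data$region) |>
    summarise(genome_bp = sum(.data$bp), .groups = "drop")
  genome <- genome[match(region_levels, genome$region), ]
  genome$genome_pct <- 100 * genome$genome_bp / sum(genome$genome_bp)

  counts <- setNames(numeric(length(region_levels)), region_levels)
  for (s in unique(reads$scaffold)) {
    p <- partition[partition$scaffold == s, ]
    if (nrow(p) == 0L) abort(sprintf("read on scaffold %s outside the partition", s))
    idx <- reads$scaffold == s
    pr <- IRanges::IRanges(p$start, p$end)
    if (weight == "midpoint") {
      mid <- reads$pos[idx] + (widths[idx] - 1L) %/% 2L
      hit <- IRanges::findOverlaps(IRanges::IRanges(mid, width = 1L), pr,
                                   select = "first")
      if (anyNA(hit)) {
        abort(sprintf("read midpoint outside scaffold %s bounds", s))
      }
      tab <- table(p$region[hit])
      counts[names(tab)] <- counts[names(tab)] + as.numeric(tab)
    } else {
      rr <- IRanges::IRanges(reads$pos[idx], width = widths[idx])
      ov <- IRanges::findOverlaps(rr, pr)
      qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
      olap <- IRanges::width(IRanges::pintersect(rr[qh], pr[sh]))
      frac <- olap / IRanges::width(rr)[qh]
      agg <- tapply(frac, p$region[sh], sum)
      counts[names(agg)] <- counts[names(agg)] + as.numeric(agg)
    }
  }
  total <- sum(counts)
  out <- tibble(
    region = region_levels,
    genome_bp = genome$genome_bp,
    genome_pct = genome$genome_pct,
    recombinant_count = as.numeric(counts),
    recombinant_pct = if (total > 0) 100 * counts / total else NA_real_,
    fold_enrichment = if (total > 0) {
      ifelse(genome$genome_pct > 0, (100 * counts / total) / genome$genome_pct,
             NA_real_)
    } else NA_real_
  )
  class(out) <- c("recombiscan_regions", class(out))
  out
}

#' @describeIn enrichment Bar chart of fold enrichment per region, with the
#'   neutral fold of 1 marked.
#' @param object,x A `recombiscan_regions` table.
#' @param ... Unused.
#' @method autoplot recombiscan_regions
#' @export
autoplot.recombiscan_regions <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$region, y = .data$fold_enrichment)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = "genomic region", y = "fold enrichment of recombinants",
                  title = "Recombinant reads vs genomic share") +
    ggplot2::theme_minimal()
}

#' @export
print.recombiscan_regions <- function(x, ...) {
  cat("Fold enrichment of recombinant reads by genomic region\n")
  NextMethod()
  invisible(x)
}
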
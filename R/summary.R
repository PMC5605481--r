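#' Summarise a sample's phased reads into recombinant/non-recombinant counts
#'
#' Aggregates read counts over all classified windows of one sample and
#' reports the recombinant and non-recombinant percentages, rounded half-up to
#' two decimals. Accepts either a classified window tibble (read counts are
#' summed per class; exact under the leading window policy, where each read
#' contributes one string) or a per-read label tibble from [label_reads()]
#' (one row per read; use this under the sliding policy).
#'
#' @param x Classified window tibble from [classify_windows()] /
#'   [filter_shared_recombinants()], or per-read labels from [label_reads()].
#' @param label Sample label stored in the summary row.
#' @return One-row tibble: `label`, `nonrecombinant_reads`,
#'   `recombinant_reads`, `total_reads`, `nonrecombinant_pct`,
#'   `recombinant_pct`. With zero total reads the percentages are `NA`.
#' @examples
#' w <- tibble::tibble(class = c("parental", "recombinant"),
#'                     n_reads = c(401623L, 21336L))
#' summarize_sample(w, "filtered heterokaryon") # 94.96 / 5.04
#' @export
summarize_sample <- function(x, label = "sample") {
  if (!"class" %in% names(x)) {
    abort("`x` must carry a `class` column (parental/recombinant)")
  }
  w <- if ("n_reads" %in% names(x)) x$n_reads else rep(1L, nrow(x))
  rec <- sum(w[x$class == "recombinant"])
  nonrec <- sum(w[x$class == "parental"])
  total <- rec + nonrec
  tibble(
    label = label,
    nonrecombinant_reads = as.integer(nonrec),
    recombinant_reads = as.integer(rec),
    total_reads = as.integer(total),
    nonrecombinant_pct = if (total > 0) round_half_up(100 * nonrec / total) else NA_real_,
    recombinant_pct = if (total > 0) round_half_up(100 * rec / total) else NA_real_
  )
}

#' Assemble the four-sample recombinant summary table
#'
#' Formats the per-sample summaries into the canonical layout: one column pair
#' (read count, percentage) per sample, ordered homokaryon 1, homokaryon 2,
#' heterokaryon, filtered heterokaryon, with rows for non-recombinants (the 2
#' parental haplotypes), recombinants (the up-to-30 other window haplotypes)
#' and the total.
#'
#' @param summaries A list or row-bound tibble of the four one-row summaries
#'   from [summarize_sample()], in the column order above (names are taken
#'   from their `label` fields).
#' @return A tibble of class `recombiscan_table2` with a `category` column and
#'   `<label>_reads` / `<label>_pct` columns per sample.
#' @export
make_table2 <- function(summaries) {
  if (is.data.frame(summaries)) {
    rows <- summaries
  } else {
    rows <- bind_rows(summaries)
  }
  if (nrow(rows) != 4L) {
    missing_n <- 4L - nrow(rows)
    abort(sprintf("expected 4 sample summaries, got %d (%d missing: %s)",
                  nrow(rows), missing_n,
                  paste(setdiff(c("homokaryon1", "homokaryon2", "heterokaryon",
                                  "filtered_heterokaryon"), rows$label),
                        collapse = ", ")))
  }
  out <- tibble(category = c("Non-recombinants (2 haplotypes)",
                             "Recombinants (30 haplotypes)",
                             "Total"))
  for (i in seq_len(4L)) {
    lbl <- rows$label[i]
    out[[paste0(lbl, "_reads")]] <- c(rows$nonrecombinant_reads[i],
                                      rows$recombinant_reads[i],
                                      rows$total_reads[i])
    out[[paste0(lbl, "_pct")]] <- c(rows$nonrecombinant_pct[i],
                                    rows$recombinant_pct[i],
                                    if (rows$total_reads[i] > 0) 100 else NA_real_)
  }
  class(out) <- c("recombiscan_table2", class(out))
  out
}

#' @export
print.recombiscan_table2 <- function(x, ...) {
  cat("Recombinant haplotype summary (reads phased by >=5 heterozygous SNPs)\n")
  NextMethod()
  invisible(x)
}
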
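#' Extract each read's alleles at heterozygous SNP positions
#'
#' For every alignment with MAPQ at least `mapq_min`, records the read base at
#' each heterozygous SNP it overlaps. Positions where the read carries a
#' deletion, clip or ambiguity code are omitted. A called A/C/G/T base that
#' matches neither of the site's two alleles is treated as a sequencing error:
#' under the default `"drop_site"` policy only that site is dropped from the
#' read's vector, under `"drop_read"` the whole read is discarded.
#'
#' @param alignments Alignment tibble (`read_id`, `scaffold`, `pos`, `seq`,
#'   `mapq`).
#' @param snps HetSNP tibble from [call_het_snps()] (sorted by scaffold,
#'   position).
#' @param mapq_min Minimum mapping quality (default 10).
#' @param unusable How to treat read bases matching neither called allele.
#' @param reference_scaffolds Optional scaffold universe; alignments on a
#'   scaffold outside it raise an error.
#' @return Read-allele tibble: `read_id`, `scaffold`, `snp_index` (index into
#'   the scaffold's sorted SNPs), `pos`, `base`, sorted by read then position.
#'   The number of rows per read is its phased-site count.
#' @export
extract_read_alleles <- function(alignments, snps, mapq_min = 10L,
                                 unusable = c("drop_site", "drop_read"),
                                 reference_scaffolds = NULL) {
  unusable <- match.arg(unusable)
  if (!is.null(reference_scaffolds)) {
    bad <- setdiff(unique(alignments$scaffold), reference_scaffolds)
    if (length(bad) > 0L) {
      abort(sprintf("alignments name scaffold(s) outside the SNP coordinate system: %s",
                    paste(bad, collapse = ", ")))
    }
  }
  aln <- alignments[alignments$mapq >= mapq_min, ]
  scaffs <- intersect(unique(aln$scaffold), unique(snps$scaffold))
  out <- map(scaffs, function(s) {
    a <- aln[aln$scaffold == s, ]
    sn <- snps[snps$scaffold == s, ]
    sn <- sn[order(sn$pos), ]
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(a$pos, width = nchar(a$seq)),
      IRanges::IRanges(sn$pos, width = 1L)
    )
    ri <- S4Vectors::queryHits(ov)
    si <- S4Vectors::subjectHits(ov)
    if (length(ri) == 0L) return(empty_read_alleles())
    off <- sn$pos[si] - a$pos[ri] + 1L
    base <- substr(a$seq[ri], off, off)
    res <- tibble(
      read_id = a$read_id[ri], scaffold = s,
      snp_index = si, pos = sn$pos[si], base = base,
      usable = base == sn$allele1[si] | base == sn$allele2[si],
      called = base %in% DNA_BASES
    )
    # deletions/clips/Ns are silently omitted in both policies
    if (unusable == "drop_read") {
      bad_reads <- unique(res$read_id[res$called & !res$usable])
      res <- res[!res$read_id %in% bad_reads, ]
    }
    res[res$usable, c("read_id", "scaffold", "snp_index", "pos", "base")]
  }) |> list_rbind()
  if (nrow(out) == 0L) return(empty_read_alleles())
  arrange(out, .data$read_id, .data$scaffold, .data$pos)
}

empty_read_alleles <- function() {
  tibble(read_id = character(), scaffold = character(),
         snp_index = integer(), pos = integer(), base = character())
}

#' Group phased reads into k-SNP haplotype windows
#'
#' Each read phased at `k` or more heterozygous SNPs contributes haplotype
#' strings over windows of `k` consecutive phased sites. Under the default
#' `"leading"` policy a read contributes exactly one string, over its first
#' `k` phased sites, which keeps per-sample read counts additive. Under
#' `"sliding"` a read contributes every run of `k` consecutive phased sites.
#' Windows are keyed by the exact SNP position tuple so they can be compared
#' across samples.
#'
#' @param read_alleles Read-allele tibble from [extract_read_alleles()].
#' @param k Window size in SNPs (default 5; must be >= 2).
#' @param policy `"leading"` (one window per read) or `"sliding"`.
#' @return Read-window tibble: `read_id`, `scaffold`, `window_index`,
#'   `window_key` (positions joined by `:`), `haplotype` (k-character allele
#'   string), `first_pos`, `last_pos`. Attributes `k` and `policy` record the
#'   settings.
#' @export
build_windows <- function(read_alleles, k = 5L, policy = c("leading", "sliding")) {
  policy <- match.arg(policy)
  k <- as.integer(k)
  if (is.na(k) || k < 2L) abort("`k` must be an integer >= 2")
  ra <- arrange(read_alleles, .data$read_id, .data$scaffold, .data$pos)
  out <- empty_read_windows()
  if (nrow(ra) > 0L) {
    runs <- rle(ra$read_id)
    m <- runs$lengths
    read_start <- cumsum(c(1L, head(m, -1L)))
    eligible <- which(m >= k)
    if (length(eligible) > 0L) {
      if (policy == "leading") {
        g <- read_start[eligible]       # one window per eligible read
        win_rows <- rep(g, each = k) + rep(0:(k - 1L), length(g))
        win_index <- rep(1L, length(g))
      } else {
        n_win <- m[eligible] - k + 1L
        g <- unlist(lapply(seq_along(eligible), function(i) {
          read_start[eligible[i]] + seq_len(n_win[i]) - 1L
        }), use.names = FALSE)
        win_rows <- rep(g, each = k) + rep(0:(k - 1L), length(g))
        win_index <- unlist(lapply(n_win, seq_len), use.names = FALSE)
      }
      pos_m <- matrix(ra$pos[win_rows], ncol = k, byrow = TRUE)
      base_m <- matrix(ra$base[win_rows], ncol = k, byrow = TRUE)
      first_rows <- win_rows[seq(1L, length(win_rows), by = k)]
      out <- tibble(
        read_id = ra$read_id[first_rows],
        scaffold = ra$scaffold[first_rows],
        window_index = win_index,
        window_key = do.call(paste, c(split(pos_m, col(pos_m)), sep = ":")),
        haplotype = do.call(paste0, split(base_m, col(base_m))),
        first_pos = pos_m[, 1L],
        last_pos = pos_m[, k]
      )
    }
  }
  attr(out, "k") <- k
  attr(out, "policy") <- policy
  out
}

empty_read_windows <- function() {
  tibble(read_id = character(), scaffold = character(),
         window_index = integer(), window_key = character(),
         haplotype = character(), first_pos = integer(), last_pos = integer())
}

#' Classify window haplotypes as parental or recombinant
#'
#' Within each window the two most frequently observed haplotype strings are
#' designated parental; every other observed string is recombinant. Count ties
#' are broken lexicographically so classification is deterministic. A window
#' with a single observed string has one parental and no recombinants. With
#' `k` SNPs at two alleles each the universe is `2^k` strings (32 for the
#' default `k = 5`), of which at most 2 are parental and `2^k - 2` (30)
#' recombinant.
#'
#' @param read_windows Read-window tibble from [build_windows()].
#' @return Window-spectrum tibble: `scaffold`, `window_key`, `first_pos`,
#'   `last_pos`, `haplotype`, `n_reads`, `rank` (1 = most frequent) and
#'   `class` (`"parental"` or `"recombinant"`), sorted by window then rank.
#'   Attributes `k` and `policy` are carried over.
#' @examples
#' rw <- tibble::tibble(
#'   read_id = sprintf("r%02d", 1:30), scaffold = "s", window_index = 1L,
#'   window_key = "1:2:3:4:5",
#'   haplotype = rep(c("AAAAA", "CCCCC", "AACCC", "CCAAA"), c(14, 14, 1, 1)),
#'   first_pos = 1L, last_pos = 5L
#' )
#' classify_windows(rw)
#' @export
classify_windows <- function(read_windows) {
  spec <- read_windows |>
    count(.data$scaffold, .data$window_key, .data$first_pos, .data$last_pos,
          .data$haplotype, name = "n_reads") |>
    arrange(.data$scaffold, .data$first_pos, .data$window_key,
            desc(.data$n_reads), .data$haplotype) |>
    group_by(.data$scaffold, .data$window_key) |>
    mutate(rank = row_number(),
           class = c("parental", "recombinant")[(.data$rank > 2L) + 1L]) |>
    ungroup()
  attr(spec, "k") <- attr(read_windows, "k")
  attr(spec, "policy") <- attr(read_windows, "policy")
  spec
}

#' Label each phased read as parental or recombinant
#'
#' Joins reads to their windows' classification. Under the sliding policy a
#' read is recombinant if any of its windows classifies its string as
#' recombinant; under the leading policy each read has exactly one window.
#' Reads whose haplotype string was removed by
#' [filter_shared_recombinants()] are dropped.
#'
#' @param read_windows Read-window tibble from [build_windows()].
#' @param windows Classified (optionally filtered) window tibble from
#'   [classify_windows()].
#' @return Per-read tibble: `read_id`, `scaffold`, `window_key`, `haplotype`,
#'   `class`.
#' @export
label_reads <- function(read_windows, windows = classify_windows(read_windows)) {
  joined <- inner_join(
    read_windows,
    windows[, c("scaffold", "window_key", "haplotype", "class")],
    by = c("scaffold", "window_key", "haplotype")
  )
  joined |>
    group_by(.data$read_id, .data$scaffold) |>
    summarise(
      window_key = .data$window_key[1L],
      haplotype = .data$haplotype[1L],
      class = ifelse(any(.data$class == "recombinant"), "recombinant", "parental"),
      .groups = "drop"
    )
}

#' Remove heterokaryon recombinant haplotypes shared with a homokaryon
#'
#' A heterokaryon recombinant haplotype string is excluded when either
#' homokaryon has a window at the identical scaffold and identical SNP
#' position tuple whose spectrum contains the identical string classified as
#' recombinant there. Excluded strings are removed outright, so their reads
#' disappear from both recombinant and total counts; parental heterokaryon
#' strings are never removed, and heterokaryon windows without a
#' same-positioned homokaryon window are retained unfiltered.
#'
#' @param het Classified window tibble of the heterokaryon.
#' @param hom1,hom2 Classified window tibbles of the two homokaryons, on the
#'   same reference coordinates.
#' @return `het` without the shared recombinant strings. The removed rows are
#'   attached as attribute `"excluded"`.
#' @export
filter_shared_recombinants <- function(het, hom1, hom2) {
  hom <- bind_rows(hom1, hom2)
  hom_rec <- hom[hom$class == "recombinant", ]
  key <- function(x) paste(x$scaffold, x$window_key, x$haplotype, sep = "\r")
  shared <- het$class == "recombinant" & key(het) %in% key(hom_rec)
  out <- het[!shared, ]
  attr(out, "excluded") <- het[shared, ]
  attr(out, "k") <- attr(het, "k")
  attr(out, "policy") <- attr(het, "policy")
  out
}

#' Enumerate the haplotype-string universe of a k-SNP window
#'
#' With two alleles per site, a window of `k` heterozygous SNPs admits `2^k`
#' strings: two complementary parental strings and `2^k - 2` recombinants.
#'
#' @param allele1,allele2 Character vectors (length `k`) of the two alleles at
#'   each site.
#' @return Character vector of all `2^k` strings, sorted.
#' @examples
#' length(enumerate_window_haplotypes(rep("A", 5), rep("C", 5))) # 32
#' @export
enumerate_window_haplotypes <- function(allele1, allele2) {
  if (length(allele1) != length(allele2)) {
    abort("allele vectors must have equal length")
  }
  grid <- expand.grid(map2(allele1, allele2, c), stringsAsFactors = FALSE)
  sort(do.call(paste0, grid))
}

#' Expected read classes from simulator ground truth
#'
#' A phased read is expected to classify as recombinant exactly when its
#' source molecule carries a crossover whose breakpoint falls strictly inside
#' the read's haplotype window (between the first and last window SNP); a
#' crossover outside the window leaves the windowed string parental. This is
#' the oracle against which pipeline calls are checked on simulated data.
#'
#' @param read_windows Read-window tibble from [build_windows()].
#' @param reads Simulated read tibble from [simulate_reads()] (truth columns
#'   `source` and `breakpoint`).
#' @return Per-read tibble `read_id`, `scaffold`, `expected_class`.
#' @export
expected_read_classes <- function(read_windows, reads) {
  truth <- reads[, c("read_id", "source", "breakpoint")]
  joined <- inner_join(read_windows, truth, by = "read_id")
  joined |>
    mutate(rec = !is.na(.data$breakpoint) &
             .data$breakpoint > .data$first_pos &
             .data$breakpoint < .data$last_pos) |>
    group_by(.data$read_id, .data$scaffold) |>
    summarise(expected_class = ifelse(any(.data$rec), "recombinant", "parental"),
              .groups = "drop")
}

#' Expected recombinant read fraction under the generative model
#'
#' Combines the truth-label expectation (reads whose source molecule's
#' crossover falls inside their haplotype window) with the error-model
#' inflation term: a substitution error at one of a window's `k` sites turns
#' into the site's other allele with probability 1/3, producing a
#' recombinant-looking string from a parental molecule, so a parental read
#' misclassifies with probability `p_flip = 1 - (1 - error_rate/3)^k`. Both
#' terms are derived from the simulator's ground truth and stated error model,
#' never from the pipeline's output, so the result is a valid expectation to
#' recover.
#'
#' @inheritParams expected_read_classes
#' @param error_rate Per-base substitution rate used in the simulation.
#' @param k Window size in SNPs.
#' @return A list: `n` phased reads, `p_truth` (truth-label fraction),
#'   `p_flip` (error inflation term), `p_expected` (combined), `sd`
#'   (binomial standard deviation of an observed fraction at `p_expected`).
#' @export
expected_recombinant_fraction <- function(read_windows, reads, error_rate,
                                          k = 5L) {
  exp_cls <- expected_read_classes(read_windows, reads)
  n <- nrow(exp_cls)
  p_truth <- if (n > 0) mean(exp_cls$expected_class == "recombinant") else NA_real_
  p_flip <- 1 - (1 - error_rate / 3)^k
  p_expected <- p_truth + (1 - p_truth) * p_flip
  list(n = n, p_truth = p_truth, p_flip = p_flip, p_expected = p_expected,
       sd = if (n > 0) sqrt(p_expected * (1 - p_expected) / n) else NA_real_)
}
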
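#' Build a MAPQ-filtered pileup
#'
#' Counts A/C/G/T read bases at every covered reference position, skipping
#' alignments whose mapping quality is below `mapq_min` (an alignment with
#' MAPQ exactly `mapq_min` is kept). Deleted reference bases, clipped bases
#' and ambiguity codes contribute nothing. Accepts either an in-memory
#' alignment tibble (e.g. from [simulate_reads()] or [read_alignments()]) or a
#' path to a BAM/SAM file, in which case counting is delegated to
#' `Rsamtools::pileup()`.
#'
#' @param x Alignment tibble (`read_id`, `scaffold`, `pos`, `seq`, `mapq`) or
#'   a BAM/SAM path.
#' @param mapq_min Minimum mapping quality; alignments below it are skipped
#'   (default 10).
#' @param ... Passed to methods.
#' @return Pileup tibble: `scaffold`, `pos`, counts `A`, `C`, `G`, `T` and
#'   `depth` (their sum), one row per covered position, sorted by scaffold
#'   then position.
#' @examples
#' aln <- tibble::tibble(
#'   read_id = c("r1", "r2", "r3"), scaffold = "s",
#'   pos = 100L, seq = c("A", "A", "C"), mapq = c(9L, 10L, 60L)
#' )
#' build_pileup(aln) # MAPQ 9 skipped: depth 2
#' @export
build_pileup <- function(x, mapq_min = 10L, ...) {
  UseMethod("build_pileup")
}

#' @rdname build_pileup
#' @export
build_pileup.data.frame <- function(x, mapq_min = 10L, ...) {
  need <- c("scaffold", "pos", "seq", "mapq")
  if (!all(need %in% names(x))) {
    abort(paste0("alignment tibble needs columns: ", paste(need, collapse = ", ")))
  }
  aln <- x[x$mapq >= mapq_min, ]
  if (nrow(aln) == 0L) return(empty_pileup())
  map(split(aln, aln$scaffold), function(a) {
    widths <- nchar(a$seq)
    pos_all <- sequence(widths, from = a$pos)
    base_all <- unlist(strsplit(a$seq, "", fixed = TRUE), use.names = FALSE)
    code <- match(base_all, DNA_BASES)           # non-ACGT (N, -) -> NA
    keep <- !is.na(code)
    pos_all <- pos_all[keep]; code <- code[keep]
    if (length(pos_all) == 0L) return(empty_pileup())
    maxpos <- max(pos_all)
    counts <- matrix(
      tabulate((pos_all - 1L) * 4L + code, nbins = 4L * maxpos),
      ncol = 4L, byrow = TRUE, dimnames = list(NULL, DNA_BASES)
    )
    covered <- which(rowSums(counts) > 0L)
    tibble(
      scaffold = a$scaffold[1], pos = covered,
      A = unname(counts[covered, "A"]), C = unname(counts[covered, "C"]),
      G = unname(counts[covered, "G"]), T = unname(counts[covered, "T"]),
      depth = as.integer(rowSums(counts[covered, , drop = FALSE]))
    )
  }) |> list_rbind() |> arrange(.data$scaffold, .data$pos)
}

#' @rdname build_pileup
#' @export
build_pileup.character <- function(x, mapq_min = 10L, ...) {
  bam <- ensure_bam(x)
  res <- Rsamtools::pileup(
    bam,
    pileupParam = Rsamtools::PileupParam(
      max_depth = 100000L, min_base_quality = 0L, min_mapq = as.integer(mapq_min),
      min_nucleotide_depth = 1L, distinguish_strands = FALSE,
      distinguish_nucleotides = TRUE, ignore_query_Ns = TRUE,
      include_deletions = FALSE, include_insertions = FALSE
    )
  )
  if (nrow(res) == 0L) return(empty_pileup())
  res <- res[res$nucleotide %in% DNA_BASES, ]
  wide <- as_tibble(res) |>
    mutate(scaffold = as.character(.data$seqnames),
           nucleotide = as.character(.data$nucleotide)) |>
    select("scaffold", "pos", "nucleotide", "count") |>
    pivot_wider(names_from = "nucleotide", values_from = "count",
                values_fill = 0L)
  for (b in DNA_BASES) if (!b %in% names(wide)) wide[[b]] <- 0L
  wide |>
    mutate(depth = .data$A + .data$C + .data$G + .data$T) |>
    select("scaffold", "pos", dplyr::all_of(DNA_BASES), "depth") |>
    arrange(.data$scaffold, .data$pos)
}

empty_pileup <- function() {
  tibble(scaffold = character(), pos = integer(),
         A = integer(), C = integer(), G = integer(), T = integer(),
         depth = integer())
}

#' Call biallelic heterozygous SNPs from a pileup
#'
#' A position is called heterozygous when all three conditions hold, each
#' boundary inclusive: total MAPQ-passing depth is at least `min_depth`; the
#' two largest allele counts `c1 >= c2` together account for at least
#' `major_frac` of the depth; and their difference is at most `max_diff` of
#' the depth. The second allele must be observed at least once. Ties among
#' allele counts are broken in base order A < C < G < T.
#'
#' @param pileup Pileup tibble from [build_pileup()].
#' @param min_depth Minimum depth (default 10, inclusive).
#' @param major_frac Minimum combined fraction of the two major alleles
#'   (default 0.90, inclusive).
#' @param max_diff Maximum allele-count difference as a fraction of depth
#'   (default 0.20, inclusive).
#' @return HetSNP tibble: `scaffold`, `pos`, `allele1` (major), `allele2`,
#'   `count1`, `count2`, `depth`.
#' @examples
#' pu <- tibble::tibble(scaffold = "s", pos = 1L,
#'                      A = 6L, C = 4L, G = 0L, T = 0L, depth = 10L)
#' call_het_snps(pu) # diff exactly 20%: called
#' @export
call_het_snps <- function(pileup, min_depth = 10L, major_frac = 0.90,
                          max_diff = 0.20) {
  if (nrow(pileup) == 0L) return(empty_hetsnps())
  m <- as.matrix(pileup[, DNA_BASES])
  storage.mode(m) <- "integer"
  # major allele: largest count, ties to the earlier base (A<C<G<T)
  i1 <- max.col(m, ties.method = "first")
  c1 <- m[cbind(seq_len(nrow(m)), i1)]
  m2 <- m
  m2[cbind(seq_len(nrow(m)), i1)] <- -1L
  i2 <- max.col(m2, ties.method = "first")
  c2 <- m[cbind(seq_len(nrow(m)), i2)]
  depth <- pileup$depth
  called <- depth >= min_depth &
    c2 >= 1L &
    (c1 + c2) >= major_frac * depth - FRAC_EPS &
    (c1 - c2) <= max_diff * depth + FRAC_EPS
  tibble(
    scaffold = pileup$scaffold[called],
    pos = pileup$pos[called],
    allele1 = DNA_BASES[i1[called]],
    allele2 = DNA_BASES[i2[called]],
    count1 = c1[called],
    count2 = c2[called],
    depth = as.integer(depth[called])
  )
}

empty_hetsnps <- function() {
  tibble(scaffold = character(), pos = integer(),
         allele1 = character(), allele2 = character(),
         count1 = integer(), count2 = integer(), depth = integer())
}

#' Remove heterokaryon SNPs also detected in either homokaryon
#'
#' Heterozygous SNPs of the heterokaryon whose (scaffold, position) also
#' occurs in either homokaryon's call set are discarded; such sites are
#' suspected artifacts of duplicated or repetitive sequence rather than true
#' inter-parental differences. By default sharing is judged on position alone;
#' with `match_alleles = TRUE` a homokaryon call only removes a site when its
#' unordered allele pair is identical too.
#'
#' @param het,hom1,hom2 HetSNP tibbles from [call_het_snps()] for the
#'   heterokaryon and the two homokaryons, on the same reference coordinates.
#' @param match_alleles Require identical allele pairs for exclusion (default
#'   `FALSE`).
#' @param reference_scaffolds Optional character vector of valid scaffold
#'   names; any call set naming a scaffold outside it raises an error.
#' @return The filtered heterokaryon HetSNP tibble.
#' @export
filter_shared_snps <- function(het, hom1, hom2, match_alleles = FALSE,
                               reference_scaffolds = NULL) {
  if (!is.null(reference_scaffolds)) {
    for (nm in c("het", "hom1", "hom2")) {
      s <- get(nm)
      bad <- setdiff(unique(s$scaffold), reference_scaffolds)
      if (length(bad) > 0L) {
        abort(sprintf("%s names scaffold(s) outside the reference: %s",
                      nm, paste(bad, collapse = ", ")))
      }
    }
  }
  hom <- bind_rows(hom1, hom2)
  if (nrow(hom) == 0L || nrow(het) == 0L) return(het)
  if (match_alleles) {
    key <- function(x) {
      a <- pmin(x$allele1, x$allele2)
      b <- pmax(x$allele1, x$allele2)
      paste(x$scaffold, x$pos, a, b, sep = "\r")
    }
  } else {
    key <- function(x) paste(x$scaffold, x$pos, sep = "\r")
  }
  het[!key(het) %in% key(hom), ]
}
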
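#' Simulate a reference genome with a genic/intergenic annotation
#'
#' Draws uppercase A/C/G/T scaffolds of the configured length and places
#' non-overlapping gene intervals of `gene_length` bp so that the genic share
#' of each scaffold equals `genic_fraction` up to one gene's granularity.
#' Deterministic for a fixed `config$seed`.
#'
#' @param config A [sim_config()].
#' @param seed RNG seed for this stage; defaults to a stream derived from
#'   `config$seed`.
#' @return A list with `sequences` (named character vector of scaffold
#'   sequences) and `genes` (tibble with `scaffold`, `start`, `end`, 1-based
#'   closed intervals).
#' @examples
#' ref <- simulate_reference(sim_config(scaffold_length = 20000, seed = 3))
#' nchar(ref$sequences)
#' @export
simulate_reference <- function(config, seed = stage_seed(config, "reference")) {
  validate_sim_config(config)
  withr::with_seed(seed, {
    scaffolds <- sprintf("scaffold_%02d", seq_len(config$n_scaffolds))
    sequences <- vapply(
      scaffolds,
      function(s) paste(sample(DNA_BASES, config$scaffold_length, replace = TRUE),
                        collapse = ""),
      character(1)
    )
    genes <- map(scaffolds, function(s) {
      slots <- config$scaffold_length %/% config$gene_length
      n_genes <- round(config$genic_fraction * config$scaffold_length /
                         config$gene_length)
      n_genes <- min(n_genes, slots)
      if (n_genes == 0L) {
        return(tibble(scaffold = character(), start = integer(), end = integer()))
      }
      pick <- sort(sample.int(slots, n_genes))
      tibble(
        scaffold = s,
        start = (pick - 1L) * config$gene_length + 1L,
        end = pick * config$gene_length
      )
    }) |> list_rbind()
    list(sequences = sequences, genes = genes)
  })
}

#' Simulate the two parental haplotypes and their heterozygous SNP table
#'
#' Parental haplotype 1 is the reference itself, so simulated reads are
#' trivially exact alignments and the pipeline is decoupled from any external
#' aligner. Parental haplotype 2 differs from the reference at exactly the SNP
#' positions. The SNP count per scaffold is Binomial(scaffold_length,
#' snp_rate); positions are grouped into clusters of about
#' `config$snp_cluster_size` sites separated by small gaps, emulating the
#' locally dense heterozygosity of highly variable fungal genomes that makes
#' five-SNP read phasing possible at all.
#'
#' @inheritParams simulate_reference
#' @param reference Output of [simulate_reference()].
#' @return A list with `snp_table` (tibble: `scaffold`, `pos`, `allele1`,
#'   `allele2`, sorted by scaffold then position), `parental1` and `parental2`
#'   (named character vectors of haplotype sequences).
#' @export
simulate_haplotypes <- function(reference, config,
                                seed = stage_seed(config, "haplotypes")) {
  validate_sim_config(config)
  withr::with_seed(seed, {
    snp_table <- map(names(reference$sequences), function(s) {
      L <- nchar(reference$sequences[[s]])
      n_snp <- rbinom(1L, L, config$snp_rate)
      if (n_snp == 0L) {
        return(tibble(scaffold = character(), pos = integer(),
                      allele1 = character(), allele2 = character()))
      }
      pos <- place_clustered_snps(n_snp, L, config)
      ref_base <- strsplit(reference$sequences[[s]], "", fixed = TRUE)[[1]][pos]
      alt_base <- vapply(ref_base,
                         function(b) sample(setdiff(DNA_BASES, b), 1L),
                         character(1), USE.NAMES = FALSE)
      tibble(scaffold = s, pos = as.integer(pos),
             allele1 = ref_base, allele2 = alt_base)
    }) |> list_rbind() |> arrange(.data$scaffold, .data$pos)

    parental2 <- reference$sequences
    for (s in unique(snp_table$scaffold)) {
      chars <- strsplit(parental2[[s]], "", fixed = TRUE)[[1]]
      rows <- snp_table$scaffold == s
      chars[snp_table$pos[rows]] <- snp_table$allele2[rows]
      parental2[[s]] <- paste(chars, collapse = "")
    }
    list(snp_table = snp_table,
         parental1 = reference$sequences,
         parental2 = parental2)
  })
}

# place n_snp positions in clusters of ~cluster_size with small intra-cluster
# gaps; clusters are scattered over equal-width blocks so positions stay
# sorted, unique and within [1, L]
place_clustered_snps <- function(n_snp, L, config) {
  csize <- max(1L, config$snp_cluster_size)
  n_clusters <- ceiling(n_snp / csize)
  sizes <- rep(n_snp %/% n_clusters, n_clusters)
  extra <- n_snp - sum(sizes)
  if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  block <- L %/% n_clusters
  lo <- config$snp_cluster_spacing[1]
  hi <- config$snp_cluster_spacing[2]
  max_span <- (csize) * hi + 1L
  if (block <= max_span + 1L) {
    # scaffold too dense for clustering: fall back to uniform unique positions
    return(sort(sample.int(L, n_snp)))
  }
  pos <- integer(0)
  for (j in seq_len(n_clusters)) {
    gaps <- if (sizes[j] > 1L) sample(lo:hi, sizes[j] - 1L, replace = TRUE) else integer(0)
    span <- sum(gaps)
    offset <- sample.int(block - span - 1L, 1L)
    start <- (j - 1L) * block + offset
    pos <- c(pos, start + cumsum(c(0L, gaps)))
  }
  sort(unique(pos))
}

#' Simulate the pool of source molecules, including crossover recombinants
#'
#' Each molecule is a full-length copy of one scaffold: a parental haplotype
#' or, with probability `recomb_fraction`, a single-crossover mosaic of the
#' two parentals. The crossover interval is drawn uniformly among the
#' inter-SNP intervals and the breakpoint uniformly within it; breakpoints are
#' recorded at half-integer coordinates so they fall strictly between two
#' adjacent SNP positions. Non-recombinant molecules are split between the two
#' parentals according to `parental_mix` (even by default). An `inject` table
#' adds stated recombinant haplotypes to the pool, which makes it possible to
#' plant the same recombinant haplotype into a homokaryon-like sample and so
#' exercise the cross-sample shared-recombinant filter.
#'
#' @inheritParams simulate_reference
#' @param snp_table SNP tibble from [simulate_haplotypes()].
#' @param scaffolds Scaffold names to populate; defaults to those in
#'   `snp_table`.
#' @param n_molecules Molecules per scaffold.
#' @param recomb_fraction Per-molecule crossover probability in `[0, 1]`.
#' @param parental_mix Length-2 non-negative weights for parental 1 vs 2 among
#'   non-recombinant molecules; `c(1, 0)` gives a homokaryon-like pool.
#' @param inject Optional tibble (`scaffold`, `breakpoint`, `left_parent`,
#'   `n`) of recombinant molecules to add verbatim, e.g. from
#'   [make_crossover()].
#' @return Tibble of molecules: `molecule_id`, `scaffold`, `source`
#'   (`"parental1"`, `"parental2"`, `"recombinant-<i>"`, `"injected-<i>"`),
#'   `left_parent` (1 or 2; `NA` for parentals), `breakpoint` (half-integer;
#'   `NA` for parentals).
#' @export
simulate_recombinant_pool <- function(snp_table, config,
                                      scaffolds = unique(snp_table$scaffold),
                                      n_molecules = config$n_molecules,
                                      recomb_fraction = config$recomb_fraction,
                                      parental_mix = c(0.5, 0.5),
                                      inject = NULL,
                                      seed = stage_seed(config, "pool")) {
  validate_sim_config(config)
  if (recomb_fraction < 0 || recomb_fraction > 1) {
    stop_field("recomb_fraction", "must be in [0, 1]")
  }
  if (length(parental_mix) != 2L || any(parental_mix < 0) || sum(parental_mix) == 0) {
    stop_field("parental_mix", "must be two non-negative weights, not both zero")
  }
  withr::with_seed(seed, {
    pool <- map(scaffolds, function(s) {
      snp_pos <- snp_table$pos[snp_table$scaffold == s]
      is_rec <- runif(n_molecules) < recomb_fraction
      if (any(is_rec) && length(snp_pos) < 2L) {
        abort(sprintf(
          "scaffold %s has %d SNP(s); crossovers need at least 2 (recomb_fraction > 0)",
          s, length(snp_pos)
        ))
      }
      source <- ifelse(is_rec, "", sample(c("parental1", "parental2"),
                                          n_molecules, replace = TRUE,
                                          prob = parental_mix / sum(parental_mix)))
      n_rec <- sum(is_rec)
      breakpoint <- rep(NA_real_, n_molecules)
      left_parent <- rep(NA_integer_, n_molecules)
      if (n_rec > 0L) {
        iv <- sample.int(length(snp_pos) - 1L, n_rec, replace = TRUE)
        # switch base uniform in (pos[i], pos[i+1]]; recorded at -0.5 so the
        # breakpoint is strictly between the two adjacent SNPs
        switch_base <- snp_pos[iv] + 1L +
          floor(runif(n_rec) * (snp_pos[iv + 1L] - snp_pos[iv]))
        breakpoint[is_rec] <- switch_base - 0.5
        left_parent[is_rec] <- sample(1:2, n_rec, replace = TRUE)
        source[is_rec] <- sprintf("recombinant-%d", seq_len(n_rec))
      }
      out <- tibble(
        molecule_id = sprintf("%s:m%06d", s, seq_len(n_molecules)),
        scaffold = s, source = source,
        left_parent = left_parent, breakpoint = breakpoint
      )
      out
    }) |> list_rbind()

    if (!is.null(inject) && nrow(inject) > 0L) {
      inj <- as_tibble(inject)
      req <- c("scaffold", "breakpoint", "left_parent", "n")
      if (!all(req %in% names(inj))) {
        abort("`inject` needs columns scaffold, breakpoint, left_parent, n")
      }
      inj_rows <- inj[rep(seq_len(nrow(inj)), inj$n), ]
      pool <- bind_rows(pool, tibble(
        molecule_id = sprintf("%s:inj%04d", inj_rows$scaffold,
                              seq_len(nrow(inj_rows))),
        scaffold = inj_rows$scaffold,
        source = sprintf("injected-%d", seq_len(nrow(inj_rows))),
        left_parent = as.integer(inj_rows$left_parent),
        breakpoint = inj_rows$breakpoint
      ))
    }
    pool
  })
}

#' Describe a crossover in a given inter-SNP interval
#'
#' Convenience constructor for the `inject` argument of
#' [simulate_recombinant_pool()]: places the breakpoint at the midpoint of the
#' interval between SNP number `after` and `after + 1` of `scaffold`, so the
#' identical recombinant haplotype can be planted into several samples.
#'
#' @param snp_table SNP tibble from [simulate_haplotypes()].
#' @param scaffold Scaffold name.
#' @param after Index (1-based, within the scaffold's sorted SNPs) of the SNP
#'   immediately left of the crossover.
#' @param left_parent Parental haplotype (1 or 2) carried left of the
#'   breakpoint.
#' @param n Number of molecules to inject (split evenly over the two
#'   orientations when `reciprocal`).
#' @param reciprocal Inject both reciprocal crossover products (`n/2` each),
#'   as a true meiotic exchange produces; this leaves the sample's per-site
#'   allele balance untouched, whereas a large one-sided injection skews the
#'   balance and can suppress heterozygous SNP calls genome-wide.
#' @return Tibble (one or two rows) suitable for `inject`.
#' @export
make_crossover <- function(snp_table, scaffold, after, left_parent = 1L,
                           n = 1L, reciprocal = FALSE) {
  pos <- snp_table$pos[snp_table$scaffold == scaffold]
  if (after < 1L || after >= length(pos)) {
    abort(sprintf("`after` must be in [1, %d] for scaffold %s",
                  length(pos) - 1L, scaffold))
  }
  bp <- (pos[after] + pos[after + 1L]) / 2
  if (reciprocal) {
    half <- as.integer(n) %/% 2L
    tibble(scaffold = scaffold, breakpoint = bp,
           left_parent = c(1L, 2L), n = c(half, as.integer(n) - half))
  } else {
    tibble(scaffold = scaffold, breakpoint = bp,
           left_parent = as.integer(left_parent), n = as.integer(n))
  }
}

#' Simulate error-bearing aligned reads from a molecule pool
#'
#' Reads are drawn in pairs: each pair samples one molecule uniformly from the
#' scaffold's pool and emits two reads with independent uniform start
#' positions (mates are treated as independent reads throughout the pipeline).
#' The number of pairs per scaffold is `round(mean_depth * L / (2 *
#' read_length))`, so total aligned bases match the requested depth.
#' Substitution errors hit each base independently at `error_rate`; a stated
#' fraction of reads receives MAPQ below 10 to exercise the mapping-quality
#' filter. Every read is a full-length exact-coordinate alignment to the
#' reference (parental haplotype 1), with its source molecule recorded as
#' ground truth.
#'
#' @inheritParams simulate_reference
#' @param molecules Molecule tibble from [simulate_recombinant_pool()].
#' @param reference Named character vector of scaffold sequences (parental 1).
#' @param snp_table SNP tibble from [simulate_haplotypes()].
#' @return Tibble of aligned reads: `read_id`, `scaffold`, `pos` (1-based
#'   leftmost), `seq`, `mapq`, plus truth columns `molecule_id`, `source`,
#'   `left_parent`, `breakpoint`.
#' @export
simulate_reads <- function(molecules, reference, snp_table, config,
                           seed = stage_seed(config, "reads")) {
  validate_sim_config(config)
  R0 <- config$read_length
  withr::with_seed(seed, {
    map(unique(molecules$scaffold), function(s) {
      ref_seq <- reference[[s]]
      if (is.null(ref_seq)) abort(sprintf("scaffold %s absent from reference", s))
      L <- nchar(ref_seq)
      if (L < R0) {
        abort(sprintf("read_length %d exceeds scaffold %s length %d", R0, s, L))
      }
      mols <- molecules[molecules$scaffold == s, ]
      n_pairs <- max(1L, round(config$mean_depth * L / (2 * R0)))
      n_reads <- 2L * n_pairs
      mol_idx <- rep(sample.int(nrow(mols), n_pairs, replace = TRUE), each = 2L)
      start <- sample.int(L - R0 + 1L, n_reads, replace = TRUE)
      seqs <- substring(ref_seq, start, start + R0 - 1L)

      # haplotype substitutions: sites where the source molecule carries the
      # parental-2 allele
      snp <- snp_table[snp_table$scaffold == s, ]
      edit_read <- integer(0); edit_off <- integer(0); edit_chr <- character(0)
      if (nrow(snp) > 0L) {
        ov <- IRanges::findOverlaps(
          IRanges::IRanges(start, width = R0),
          IRanges::IRanges(snp$pos, width = 1L)
        )
        ri <- S4Vectors::queryHits(ov)
        si <- S4Vectors::subjectHits(ov)
        src <- mols$source[mol_idx[ri]]
        lp <- mols$left_parent[mol_idx[ri]]
        bp <- mols$breakpoint[mol_idx[ri]]
        parent_at <- ifelse(src == "parental1", 1L,
                     ifelse(src == "parental2", 2L,
                            ifelse(snp$pos[si] < bp, lp, 3L - lp)))
        alt <- parent_at == 2L
        edit_read <- ri[alt]
        edit_off <- snp$pos[si[alt]] - start[ri[alt]] + 1L
        edit_chr <- snp$allele2[si[alt]]
      }

      # sequencing errors: per-base substitutions to a different base
      n_err <- rbinom(n_reads, R0, config$error_rate)
      err_read <- rep(seq_len(n_reads), n_err)
      err_off <- unlist(lapply(n_err[n_err > 0L],
                               function(k) sample.int(R0, k)), use.names = FALSE)
      if (is.null(err_off)) err_off <- integer(0)

      touched <- unique(c(edit_read, err_read))
      if (length(touched) > 0L) {
        chars <- strsplit(seqs[touched], "", fixed = TRUE)
        names(chars) <- as.character(touched)
        for (i in seq_along(edit_read)) {
          chars[[as.character(edit_read[i])]][edit_off[i]] <- edit_chr[i]
        }
        for (i in seq_along(err_read)) {
          v <- chars[[as.character(err_read[i])]]
          v[err_off[i]] <- sample(setdiff(DNA_BASES, v[err_off[i]]), 1L)
          chars[[as.character(err_read[i])]] <- v
        }
        seqs[touched] <- vapply(chars, paste, character(1), collapse = "")
      }

      low <- runif(n_reads) < config$low_mapq_fraction
      mapq <- ifelse(low, sample(0:9, n_reads, replace = TRUE), config$mapq_high)

      tibble(
        read_id = sprintf("%s_p%06d_%d", s, rep(seq_len(n_pairs), each = 2L),
                          rep(1:2, n_pairs)),
        scaffold = s,
        pos = as.integer(start),
        seq = seqs,
        mapq = as.integer(mapq),
        molecule_id = mols$molecule_id[mol_idx],
        source = mols$source[mol_idx],
        left_parent = mols$left_parent[mol_idx],
        breakpoint = mols$breakpoint[mol_idx]
      )
    }) |> list_rbind()
  })
}

#' Simulate a heterokaryon plus its two parental homokaryons
#'
#' One call produces the whole study design: a shared reference and SNP table,
#' a heterokaryon sample whose molecule pool mixes the two parental
#' haplotypes evenly with `config$recomb_fraction` single-crossover
#' recombinants, and two homokaryon samples that by default carry a single
#' parental haplotype each (so they yield no heterozygous SNPs). Injection
#' arguments plant stated recombinant haplotypes into any sample, e.g. to
#' recreate the scenario where one recombinant haplotype is unique to the
#' heterokaryon and another is shared with a homokaryon.
#'
#' @inheritParams simulate_reference
#' @param inject_het,inject_hom1,inject_hom2 Optional crossover tables (see
#'   [make_crossover()]) injected into the respective sample's pool.
#' @param hom1_parental_mix,hom2_parental_mix Parental weights of the
#'   homokaryon pools. The defaults `c(1, 0)` / `c(0, 1)` are true
#'   homokaryons; an even mix emulates a duplicated region carrying both
#'   haplotypes, which makes the homokaryon callable at the shared SNPs.
#' @param hom_recomb_fraction Crossover fraction of the homokaryon pools
#'   (default 0).
#' @return A list with `config`, `reference` (sequences + genes),
#'   `haplotypes` (snp_table + the two parental sequences) and `samples`, a
#'   named list (`heterokaryon`, `homokaryon1`, `homokaryon2`) of
#'   `list(molecules, reads)`.
#' @examples
#' trio <- simulate_trio(sim_config(scaffold_length = 20000, mean_depth = 10,
#'                                  seed = 42))
#' names(trio$samples)
#' @export
simulate_trio <- function(config,
                          inject_het = NULL,
                          inject_hom1 = NULL,
                          inject_hom2 = NULL,
                          hom1_parental_mix = c(1, 0),
                          hom2_parental_mix = c(0, 1),
                          hom_recomb_fraction = 0) {
  validate_sim_config(config)
  reference <- simulate_reference(config)
  haplotypes <- simulate_haplotypes(reference, config)
  scaffolds <- names(reference$sequences)

  sample_spec <- list(
    heterokaryon = list(mix = c(0.5, 0.5), frac = config$recomb_fraction,
                        inject = inject_het, offset = 0L),
    homokaryon1 = list(mix = hom1_parental_mix, frac = hom_recomb_fraction,
                       inject = inject_hom1, offset = 17L),
    homokaryon2 = list(mix = hom2_parental_mix, frac = hom_recomb_fraction,
                       inject = inject_hom2, offset = 34L)
  )
  samples <- purrr::imap(sample_spec, function(sp, nm) {
    molecules <- simulate_recombinant_pool(
      haplotypes$snp_table, config, scaffolds = scaffolds,
      recomb_fraction = sp$frac, parental_mix = sp$mix, inject = sp$inject,
      seed = stage_seed(config, "pool") + sp$offset
    )
    reads <- simulate_reads(
      molecules, reference$sequences, haplotypes$snp_table, config,
      seed = stage_seed(config, "reads") + sp$offset
    )
    list(molecules = molecules, reads = reads)
  })

  list(config = config, reference = reference, haplotypes = haplotypes,
       samples = samples)
}
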
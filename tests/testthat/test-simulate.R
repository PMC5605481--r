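test_that("config validation names the offending field", {
  expect_error(sim_config(scaffold_length = 0), "scaffold_length")
  expect_error(sim_config(scaffold_length = 100, read_length = 250),
               "scaffold_length")
  expect_error(sim_config(recomb_fraction = 1.5), "recomb_fraction")
  expect_error(sim_config(error_rate = -0.1), "error_rate")
  expect_error(sim_config(snp_rate = 1e-5, scaffold_length = 50000), "snp_rate")
})

test_that("identical configs give byte-identical simulation outputs", {
  cfg <- small_config(seed = 7)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  p1 <- write_sim_outputs(simulate_trio(cfg), d1)
  p2 <- write_sim_outputs(simulate_trio(cfg), d2)
  expect_identical(unname(tools::md5sum(sort(unname(p1)))),
                   unname(tools::md5sum(sort(unname(p2)))))
})

test_that("genic share of the annotation matches the configured fraction", {
  cfg <- sim_config(scaffold_length = 100000L, genic_fraction = 0.4, seed = 2)
  ref <- simulate_reference(cfg)
  genic_bp <- sum(ref$genes$end - ref$genes$start + 1)
  expect_lt(abs(genic_bp / cfg$scaffold_length - 0.4), 0.01)
  expect_true(all(ref$genes$start >= 1 & ref$genes$end <= cfg$scaffold_length))
  expect_equal(nchar(ref$sequences), c(scaffold_01 = 100000L))
  expect_false(grepl("[^ACGT]", ref$sequences[[1]]))
})

test_that("haplotype simulation honours the SNP rate and allele structure", {
  cfg <- sim_config(scaffold_length = 100000L, snp_rate = 1e-3, seed = 5)
  ref <- simulate_reference(cfg)
  hap <- simulate_haplotypes(ref, cfg)
  # count is Binomial(1e5, 1e-3): mean 100, 3 SD ~ 30
  expect_lt(abs(nrow(hap$snp_table) - 100), 30)
  expect_true(all(hap$snp_table$allele1 != hap$snp_table$allele2))
  expect_identical(hap$parental1, ref$sequences)
  # parental 2 differs from the reference exactly at SNP positions
  c1 <- strsplit(hap$parental1[[1]], "")[[1]]
  c2 <- strsplit(hap$parental2[[1]], "")[[1]]
  expect_identical(which(c1 != c2), as.integer(hap$snp_table$pos))
  expect_identical(c2[hap$snp_table$pos], hap$snp_table$allele2)
})

test_that("snp_rate zero gives an identical second haplotype", {
  cfg <- sim_config(scaffold_length = 20000L, snp_rate = 0, seed = 1)
  hap <- simulate_haplotypes(simulate_reference(cfg), cfg)
  expect_identical(nrow(hap$snp_table), 0L)
  expect_identical(hap$parental1, hap$parental2)
})

test_that("recombinant fraction of the molecule pool is binomial", {
  cfg <- small_config(seed = 3)
  hap <- simulate_haplotypes(simulate_reference(cfg), cfg)
  all_par <- simulate_recombinant_pool(hap$snp_table, cfg, recomb_fraction = 0)
  expect_true(all(all_par$source %in% c("parental1", "parental2")))
  expect_true(all(is.na(all_par$breakpoint)))

  all_rec <- simulate_recombinant_pool(hap$snp_table, cfg, recomb_fraction = 1)
  expect_true(all(grepl("^recombinant-", all_rec$source)))
  expect_true(all(!is.na(all_rec$breakpoint)))

  pool <- simulate_recombinant_pool(hap$snp_table, cfg, n_molecules = 10000L,
                                    recomb_fraction = 0.05)
  n_rec <- sum(grepl("^recombinant-", pool$source))
  expect_lt(abs(n_rec - 500), 3 * sqrt(10000 * 0.05 * 0.95))
})

test_that("breakpoints fall strictly between adjacent SNPs", {
  cfg <- small_config(seed = 9)
  hap <- simulate_haplotypes(simulate_reference(cfg), cfg)
  pool <- simulate_recombinant_pool(hap$snp_table, cfg, recomb_fraction = 0.3)
  bp <- pool$breakpoint[!is.na(pool$breakpoint)]
  pos <- hap$snp_table$pos
  idx <- findInterval(bp, pos)
  expect_true(all(idx >= 1 & idx < length(pos)))
  expect_true(all(bp > pos[idx] & bp < pos[idx + 1]))
  expect_false(any(bp %in% pos))
})

test_that("read simulation hits the requested depth and MAPQ mix", {
  cfg <- sim_config(scaffold_length = 100000L, mean_depth = 35,
                    low_mapq_fraction = 0.1, seed = 13)
  ref <- simulate_reference(cfg)
  hap <- simulate_haplotypes(ref, cfg)
  pool <- simulate_recombinant_pool(hap$snp_table, cfg)
  reads <- simulate_reads(pool, ref$sequences, hap$snp_table, cfg)
  depth <- sum(nchar(reads$seq)) / cfg$scaffold_length
  expect_lt(abs(depth - 35) / 35, 0.1)
  frac_low <- mean(reads$mapq < 10)
  expect_lt(abs(frac_low - 0.1), 3 * sqrt(0.1 * 0.9 / nrow(reads)))
  expect_true(all(reads$mapq[reads$mapq >= 10] == cfg$mapq_high))
  expect_false(any(duplicated(reads$read_id)))
  # conservation: every read points at an existing molecule
  expect_true(all(reads$molecule_id %in% pool$molecule_id))
})

test_that("error-free reads match their source molecule exactly", {
  cfg <- small_config(seed = 21, error_rate = 0, recomb_fraction = 0.2)
  ref <- simulate_reference(cfg)
  hap <- simulate_haplotypes(ref, cfg)
  pool <- simulate_recombinant_pool(hap$snp_table, cfg)
  reads <- simulate_reads(pool, ref$sequences, hap$snp_table, cfg)
  # independent oracle: rebuild each distinct molecule sequence from the SNP
  # table and compare every read to the corresponding substring
  take <- reads[seq_len(200L), ]
  mol_seqs <- new.env()
  for (i in seq_len(nrow(take))) {
    r <- take[i, ]
    if (is.null(mol_seqs[[r$molecule_id]])) {
      mol <- pool[pool$molecule_id == r$molecule_id, ]
      mol_seqs[[r$molecule_id]] <- molecule_sequence(mol, ref$sequences,
                                                     hap$snp_table)
    }
    expect_identical(
      r$seq,
      substr(mol_seqs[[r$molecule_id]], r$pos, r$pos + nchar(r$seq) - 1L)
    )
  }
})

test_that("reciprocal crossover injection adds balanced labelled molecules", {
  cfg <- small_config(seed = 4)
  hap <- simulate_haplotypes(simulate_reference(cfg), cfg)
  inj <- make_crossover(hap$snp_table, "scaffold_01", after = 3, n = 10,
                        reciprocal = TRUE)
  expect_identical(inj$left_parent, c(1L, 2L))
  expect_identical(sum(inj$n), 10L)
  pool <- simulate_recombinant_pool(hap$snp_table, cfg, recomb_fraction = 0,
                                    inject = inj)
  injected <- pool[grepl("^injected-", pool$source), ]
  expect_identical(nrow(injected), 10L)
  expect_true(all(injected$breakpoint == inj$breakpoint[1]))
  expect_error(make_crossover(hap$snp_table, "scaffold_01", after = 0), "after")
})
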
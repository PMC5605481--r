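test_that("the three-part heterozygosity rule is inclusive at every boundary", {
  cases <- list(
    # counts, called?, note
    list(pileup_row(A = 5, C = 5), TRUE),    # perfect balance at min depth
    list(pileup_row(A = 6, C = 4), TRUE),    # diff exactly 20% of depth
    list(pileup_row(A = 7, C = 3), FALSE),   # diff 40% > 20%
    list(pileup_row(A = 5, C = 4, G = 1), TRUE),  # top two exactly 90%
    list(pileup_row(A = 5, C = 4, G = 2), FALSE), # top two ~82% < 90%
    list(pileup_row(A = 5, C = 4), FALSE),   # depth 9 < 10
    list(pileup_row(A = 10), FALSE)          # no second allele
  )
  for (cs in cases) {
    called <- call_het_snps(cs[[1]])
    expect_identical(nrow(called) == 1L, cs[[2]])
  }
  snp <- call_het_snps(pileup_row(A = 6, C = 4))
  expect_identical(snp$allele1, "A")
  expect_identical(snp$allele2, "C")
  expect_identical(snp$count1, 6L)
  expect_identical(snp$count2, 4L)
})

test_that("allele ties break in base order A < C < G < T", {
  tie_major <- call_het_snps(pileup_row(C = 5, G = 5))
  expect_identical(tie_major$allele1, "C")
  expect_identical(tie_major$allele2, "G")
  # three-way tie for second place: lexicographically smallest wins
  tie_second <- call_het_snps(pileup_row(A = 14, C = 2, G = 2, T = 2),
                              major_frac = 0.5, max_diff = 0.9)
  expect_identical(nrow(tie_second), 1L)
  expect_identical(tie_second$allele2, "C")
})

test_that("tightening any threshold never enlarges the called set", {
  withr::local_seed(99)
  pu <- tibble::tibble(
    scaffold = "s", pos = 1:500,
    A = rbinom(500, 20, 0.5), C = rbinom(500, 20, 0.4),
    G = rbinom(500, 3, 0.2), T = rbinom(500, 3, 0.1)
  )
  pu$depth <- pu$A + pu$C + pu$G + pu$T
  base <- call_het_snps(pu)$pos
  for (args in list(list(min_depth = 15L), list(major_frac = 0.95),
                    list(max_diff = 0.10),
                    list(min_depth = 12L, major_frac = 0.92, max_diff = 0.15))) {
    tightened <- do.call(call_het_snps, c(list(pu), args))$pos
    expect_true(all(tightened %in% base))
  }
})

test_that("called SNPs recover truth SNPs on clean simulated data", {
  cfg <- sim_config(scaffold_length = 100000L, mean_depth = 40,
                    error_rate = 0, low_mapq_fraction = 0, seed = 8)
  trio <- simulate_trio(cfg)
  called <- call_het_snps(build_pileup(trio$samples$heterokaryon$reads))
  truth <- trio$haplotypes$snp_table
  expect_true(all(paste(called$scaffold, called$pos) %in%
                    paste(truth$scaffold, truth$pos)))
  # most truth SNPs qualify at depth 40 with balanced sampling
  expect_gt(nrow(called) / nrow(truth), 0.7)
})

test_that("heterokaryon SNPs shared with a homokaryon are removed by position", {
  het <- tibble::tibble(scaffold = "chr1", pos = c(100L, 200L),
                        allele1 = c("A", "C"), allele2 = c("C", "T"),
                        count1 = 6L, count2 = 4L, depth = 10L)
  hom1 <- het[1, ]
  hom2 <- het[0, ]
  kept <- filter_shared_snps(het, hom1, hom2)
  expect_identical(kept$pos, 200L)
  # disjoint sets pass through untouched
  hom_far <- dplyr::mutate(het, pos = pos + 1L)
  expect_identical(filter_shared_snps(het, hom_far[0, ], hom_far[0, ]), het)
  # allele-strict mode keeps a site whose alleles differ in the homokaryon
  hom_other_alleles <- dplyr::mutate(het[1, ], allele1 = "G", allele2 = "T")
  strict <- filter_shared_snps(het, hom_other_alleles, hom2,
                               match_alleles = TRUE)
  expect_identical(strict$pos, c(100L, 200L))
  loose <- filter_shared_snps(het, hom_other_alleles, hom2)
  expect_identical(loose$pos, 200L)
  expect_error(
    filter_shared_snps(het, hom1, hom2, reference_scaffolds = "chr2"),
    "scaffold"
  )
})

test_that("a duplicated-region false het in a homokaryon removes that site", {
  # emulate a duplicated region: homokaryon 1 carries both haplotypes over
  # the first third of the scaffold, so it is callable (false het) there
  cfg <- sim_config(scaffold_length = 60000L, mean_depth = 40,
                    error_rate = 0, low_mapq_fraction = 0, seed = 14)
  trio <- simulate_trio(cfg, hom1_parental_mix = c(0.5, 0.5))
  het_calls <- call_het_snps(build_pileup(trio$samples$heterokaryon$reads))
  hom1_calls <- call_het_snps(build_pileup(trio$samples$homokaryon1$reads))
  hom2_calls <- call_het_snps(build_pileup(trio$samples$homokaryon2$reads))
  expect_gt(nrow(hom1_calls), 0L)
  kept <- filter_shared_snps(het_calls, hom1_calls, hom2_calls)
  expect_false(any(paste(kept$scaffold, kept$pos) %in%
                     paste(hom1_calls$scaffold, hom1_calls$pos)))
  expect_lt(nrow(kept), nrow(het_calls))
})
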
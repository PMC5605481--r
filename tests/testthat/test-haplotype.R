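# a 6-SNP panel on scaffold "s": positions 10,20,...,60, alleles A (major,
# reference) vs C at every site
panel6 <- tibble::tibble(
  scaffold = "s", pos = seq(10L, 60L, by = 10L),
  allele1 = "A", allele2 = "C", count1 = 6L, count2 = 4L, depth = 10L
)

# a read covering [from, to] carrying `hap` ("1" = allele1/A, "2" = allele2/C)
# at the panel sites it overlaps and reference A elsewhere
panel_read <- function(id, from, to, hap, mapq = 60L, override = NULL) {
  chars <- rep("A", to - from + 1L)
  sites <- panel6$pos[panel6$pos >= from & panel6$pos <= to]
  alle <- c(`1` = "A", `2` = "C")
  chars[sites - from + 1L] <- alle[strsplit(hap, "")[[1]]]
  if (!is.null(override)) chars[override$pos - from + 1L] <- override$base
  aln_row(id, paste(chars, collapse = ""), pos = from, mapq = mapq)
}

test_that("read alleles are extracted at every overlapped SNP", {
  aln <- dplyr::bind_rows(
    panel_read("six", 5, 65, "121212"),   # spans all 6 SNPs
    panel_read("four", 15, 55, "2121"),   # spans SNPs at 20..50
    panel_read("lowq", 5, 65, "111111", mapq = 9)
  )
  ra <- extract_read_alleles(aln, panel6)
  expect_identical(sum(ra$read_id == "six"), 6L)
  expect_identical(sum(ra$read_id == "four"), 4L)
  expect_identical(sum(ra$read_id == "lowq"), 0L)
  expect_identical(ra$base[ra$read_id == "six"], c("A", "C", "A", "C", "A", "C"))
  expect_identical(ra$snp_index[ra$read_id == "four"], 2:5)
})

test_that("a base matching neither allele drops the site or the read", {
  aln <- panel_read("r", 5, 65, "111111",
                    override = list(pos = 30L, base = "G"))
  tolerant <- extract_read_alleles(aln, panel6, unusable = "drop_site")
  expect_identical(nrow(tolerant), 5L)
  expect_false(30L %in% tolerant$pos)
  strict <- extract_read_alleles(aln, panel6, unusable = "drop_read")
  expect_identical(nrow(strict), 0L)
  expect_error(
    extract_read_alleles(aln, panel6, reference_scaffolds = "other"),
    "scaffold"
  )
})

test_that("error-free reads from parental 2 carry only the second allele", {
  cfg <- small_config(seed = 17, error_rate = 0)
  trio <- simulate_trio(cfg)
  reads <- trio$samples$heterokaryon$reads
  snps <- call_het_snps(build_pileup(reads))
  ra <- extract_read_alleles(reads, snps)
  p2 <- reads$read_id[reads$source == "parental2"]
  got <- dplyr::inner_join(ra[ra$read_id %in% p2, ],
                           trio$haplotypes$snp_table,
                           by = c("scaffold", "pos"))
  expect_gt(nrow(got), 0L)
  expect_true(all(got$base == got$allele2))
})

test_that("leading windows take the first five phased sites, sliding all runs", {
  aln <- dplyr::bind_rows(
    panel_read("r5", 5, 52, "11111"),     # SNPs 10..50
    panel_read("r7", 5, 65, "111122")     # SNPs 10..60
  )
  ra <- extract_read_alleles(aln, panel6)
  lead <- build_windows(ra, k = 5, policy = "leading")
  expect_identical(nrow(lead), 2L)
  expect_identical(unique(lead$window_key), "10:20:30:40:50")
  expect_identical(lead$haplotype[lead$read_id == "r7"], "AAAAC")
  slide <- build_windows(ra, k = 5, policy = "sliding")
  expect_identical(nrow(slide), 3L)
  expect_setequal(slide$window_key[slide$read_id == "r7"],
                  c("10:20:30:40:50", "20:30:40:50:60"))
  expect_error(build_windows(ra, k = 1), "k")
})

test_that("reads phased at fewer than five SNPs contribute no window", {
  aln <- panel_read("short", 15, 55, "1111")  # 4 SNPs only
  ra <- extract_read_alleles(aln, panel6)
  expect_identical(nrow(ra), 4L)
  expect_identical(nrow(build_windows(ra)), 0L)
})

test_that("every read phased at >=5 SNPs contributes exactly one leading string", {
  cfg <- small_config(seed = 23)
  trio <- simulate_trio(cfg)
  reads <- trio$samples$heterokaryon$reads
  snps <- call_het_snps(build_pileup(reads))
  ra <- extract_read_alleles(reads, snps)
  n_eligible <- sum(table(ra$read_id) >= 5)
  rw <- build_windows(ra)
  expect_identical(nrow(rw), n_eligible)
  expect_false(any(duplicated(rw$read_id)))
  # conservation through classification
  w <- classify_windows(rw)
  expect_identical(sum(w$n_reads), n_eligible)
})

test_that("the two most frequent strings are parental, all others recombinant", {
  rw <- spectrum_windows(c(AAAAA = 14, CCCCC = 14, AACCC = 1, CCAAA = 1))
  w <- classify_windows(rw)
  expect_setequal(w$haplotype[w$class == "parental"], c("AAAAA", "CCCCC"))
  expect_identical(sum(w$n_reads[w$class == "recombinant"]), 2L)
  # a lone observed string is parental with no recombinants
  w1 <- classify_windows(spectrum_windows(c(AAAAA = 30)))
  expect_identical(w1$class, "parental")
})

test_that("classification matches a brute-force sort-by-count oracle", {
  withr::local_seed(42)
  universe <- enumerate_window_haplotypes(rep("A", 5), rep("C", 5))
  for (i in 1:20) {
    n_strings <- sample(1:8, 1)
    spec <- setNames(sample(1:20, n_strings, replace = TRUE),
                     sample(universe, n_strings))
    w <- classify_windows(spectrum_windows(spec))
    # oracle: order by count desc then string asc, take top 2 as parental
    o <- order(-spec, names(spec))
    oracle_parental <- names(spec)[o][seq_len(min(2, length(spec)))]
    expect_setequal(w$haplotype[w$class == "parental"], oracle_parental)
    expect_setequal(w$haplotype[w$class == "recombinant"],
                    setdiff(names(spec), oracle_parental))
  }
})

test_that("window universe size is 2^k with at most 2^k - 2 recombinants", {
  u5 <- enumerate_window_haplotypes(rep("A", 5), rep("G", 5))
  expect_identical(length(u5), 32L)
  expect_false(any(duplicated(u5)))
  u3 <- enumerate_window_haplotypes(c("A", "C", "G"), c("T", "G", "A"))
  expect_identical(length(u3), 8L)
  # feeding the full universe through the classifier: 2 parental, 30 recombinant
  w <- classify_windows(spectrum_windows(setNames(rep(1L, 32), u5)))
  expect_identical(sum(w$class == "parental"), 2L)
  expect_identical(sum(w$class == "recombinant"), 30L)
})

test_that("sliding policy flags a read recombinant if any window does", {
  # r1 parental everywhere; r2 recombinant in its second window only
  ra <- tibble::tibble(
    read_id = rep(c("bg1", "bg2", "bg3", "bg4", "r2"), c(6, 6, 6, 6, 6)),
    scaffold = "s",
    snp_index = rep(1:6, 5),
    pos = rep(seq(10L, 60L, 10L), 5),
    base = c(rep("A", 6), rep("A", 6), rep("C", 6), rep("C", 6),
             c("A", "A", "A", "A", "A", "C"))
  )
  rw <- build_windows(ra, policy = "sliding")
  labels <- label_reads(rw)
  expect_identical(labels$class[labels$read_id == "r2"], "recombinant")
  expect_true(all(labels$class[labels$read_id != "r2"] == "parental"))
  # each read appears once regardless of its window count
  expect_identical(nrow(labels), 5L)
})

test_that("pipeline read calls equal truth labels on clean data", {
  cfg <- small_config(seed = 29, error_rate = 0, low_mapq_fraction = 0,
                      recomb_fraction = 0.1)
  trio <- simulate_trio(cfg)
  reads <- trio$samples$heterokaryon$reads
  snps <- call_het_snps(build_pileup(reads))
  rw <- build_windows(extract_read_alleles(reads, snps))
  obs <- label_reads(rw)
  exp <- expected_read_classes(rw, reads)
  m <- dplyr::inner_join(obs, exp, by = c("read_id", "scaffold"))
  expect_identical(nrow(m), nrow(rw))
  expect_identical(m$class, m$expected_class)
})
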
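# shared fixtures: small seeded simulations and hand-built tables

small_config <- function(seed = 11, ...) {
  sim_config(scaffold_length = 50000L, mean_depth = 20, seed = seed, ...)
}

# one-row pileup column
pileup_row <- function(A = 0L, C = 0L, G = 0L, T = 0L, pos = 1L, scaffold = "s") {
  tibble::tibble(scaffold = scaffold, pos = as.integer(pos),
                 A = as.integer(A), C = as.integer(C),
                 G = as.integer(G), T = as.integer(T),
                 depth = as.integer(A + C + G + T))
}

# a full-match alignment record
aln_row <- function(read_id, seq, pos = 1L, scaffold = "s", mapq = 60L) {
  tibble::tibble(read_id = read_id, scaffold = scaffold, pos = as.integer(pos),
                 seq = seq, mapq = as.integer(mapq))
}

# read-window rows for a single window from a named spectrum, e.g.
# c(AAAAA = 14, CCCCC = 14, AACCC = 1)
spectrum_windows <- function(spectrum, scaffold = "s",
                             positions = c(10L, 20L, 30L, 40L, 50L)) {
  haps <- rep(names(spectrum), spectrum)
  tibble::tibble(
    read_id = sprintf("%s_r%04d", scaffold, seq_along(haps)),
    scaffold = scaffold,
    window_index = 1L,
    window_key = paste(positions, collapse = ":"),
    haplotype = haps,
    first_pos = positions[1],
    last_pos = positions[length(positions)]
  )
}

# reconstruct a molecule's full sequence independently of simulate_reads():
# start from the reference and substitute the parental-2 allele wherever the
# molecule carries parental 2 (by its breakpoint/orientation)
molecule_sequence <- function(molecule, reference, snp_table) {
  s <- molecule$scaffold
  chars <- strsplit(reference[[s]], "", fixed = TRUE)[[1]]
  snp <- snp_table[snp_table$scaffold == s, ]
  if (nrow(snp) == 0L) return(paste(chars, collapse = ""))
  parent_at <- if (molecule$source == "parental1") {
    rep(1L, nrow(snp))
  } else if (molecule$source == "parental2") {
    rep(2L, nrow(snp))
  } else {
    ifelse(snp$pos < molecule$breakpoint, molecule$left_parent,
           3L - molecule$left_parent)
  }
  chars[snp$pos[parent_at == 2L]] <- snp$allele2[parent_at == 2L]
  paste(chars, collapse = "")
}
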
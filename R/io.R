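#' Read aligned reads from a BAM or SAM file into an alignment tibble
#'
#' Loads alignments with `GenomicAlignments` and lays each read's query
#' sequence out in reference space (deleted reference bases become `-`,
#' insertions and clipped bases are removed), so downstream per-position
#' lookups are plain substring operations. Reads flagged unmapped are dropped.
#'
#' @param path Path to a BAM file (coordinate-sorted, or sortable) or a SAM
#'   text file.
#' @return Alignment tibble with columns `read_id`, `scaffold`, `pos`
#'   (1-based leftmost), `seq` (reference-space sequence), `mapq`.
#' @export
read_alignments <- function(path) {
  bam <- ensure_bam(path)
  param <- Rsamtools::ScanBamParam(what = c("qname", "mapq", "seq"))
  ga <- GenomicAlignments::readGAlignments(bam, param = param, use.names = FALSE)
  seqs <- GenomicAlignments::sequenceLayer(
    S4Vectors::mcols(ga)$seq,
    GenomicAlignments::cigar(ga), from = "query", to = "reference"
  )
  tibble(
    read_id = S4Vectors::mcols(ga)$qname,
    scaffold = as.character(GenomicAlignments::seqnames(ga)),
    pos = GenomicAlignments::start(ga),
    seq = as.character(seqs),
    mapq = as.integer(S4Vectors::mcols(ga)$mapq)
  )
}

# convert SAM to sorted+indexed BAM (temp file) or make sure a BAM has an
# index; errors instruct the user to sort when indexing fails
ensure_bam <- function(path) {
  if (!file.exists(path)) abort(sprintf("alignment file not found: %s", path))
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    return(Rsamtools::asBam(path, dest, overwrite = TRUE, indexDestination = TRUE))
  }
  if (!file.exists(paste0(path, ".bai")) &&
      !file.exists(sub("\\.bam$", ".bai", path))) {
    ok <- tryCatch({ Rsamtools::indexBam(path); TRUE }, error = function(e) FALSE)
    if (!ok) {
      abort(sprintf(
        "BAM %s is not coordinate-sorted and has no index; sort it first (e.g. `samtools sort`)",
        path
      ))
    }
  }
  path
}

#' Write an alignment tibble as a SAM file
#'
#' Emits mandatory-field SAM records with a full-match CIGAR and constant high
#' base qualities (the pipeline never uses base quality). Records are
#' coordinate-sorted.
#'
#' @param alignments Alignment tibble (`read_id`, `scaffold`, `pos`, `seq`,
#'   `mapq`).
#' @param reference_lengths Named integer vector of scaffold lengths for the
#'   `@SQ` header lines.
#' @param path Output path (`.sam`).
#' @return `path`, invisibly.
#' @export
write_sam <- function(alignments, reference_lengths, path) {
  aln <- arrange(alignments, .data$scaffold, .data$pos)
  header <- c(
    "@HD\tVN:1.6\tSO:coordinate",
    sprintf("@SQ\tSN:%s\tLN:%d", names(reference_lengths),
            as.integer(reference_lengths))
  )
  qual <- strrep("I", nchar(aln$seq))
  records <- sprintf("%s\t0\t%s\t%d\t%d\t%dM\t*\t0\t0\t%s\t%s",
                     aln$read_id, aln$scaffold, aln$pos, aln$mapq,
                     nchar(aln$seq), aln$seq, qual)
  writeLines(c(header, records), path)
  invisible(path)
}

#' Write scaffold sequences as FASTA
#' @param sequences Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sequences), path)
  invisible(path)
}

#' Write reads as FASTQ (Sanger qualities, constant high quality)
#' @param reads Alignment tibble with `read_id` and `seq`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  seqs <- Biostrings::DNAStringSet(gsub("-", "N", reads$seq, fixed = TRUE))
  names(seqs) <- reads$read_id
  quals <- Biostrings::BStringSet(strrep("I", Biostrings::width(seqs)))
  Biostrings::writeXStringSet(seqs, path, format = "fastq", qualities = quals)
  invisible(path)
}

#' Write gene intervals as GFF3
#' @param genes Tibble with `scaffold`, `start`, `end` (1-based closed).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genes, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = genes$scaffold,
    ranges = IRanges::IRanges(genes$start, genes$end),
    type = "gene",
    ID = sprintf("gene%05d", seq_len(nrow(genes)))
  )
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read gene intervals from a GFF3 file
#' @param path GFF3 path.
#' @param feature Feature types treated as genes.
#' @return Tibble with `scaffold`, `start`, `end`, `type`.
#' @export
read_gff3 <- function(path, feature = c("gene", "exon", "intron")) {
  gr <- rtracklayer::import(path, format = "gff3")
  keep <- as.character(gr$type) %in% feature
  gr <- gr[keep]
  tibble(
    scaffold = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    type = as.character(gr$type)
  )
}

#' Write called heterozygous SNPs as a minimal VCF
#'
#' One record per site: REF is the major allele, ALT the second allele, INFO
#' carries total MAPQ-passing depth (`DP`) and the two allele counts (`AD`).
#'
#' @param snps HetSNP tibble from [call_het_snps()].
#' @param path Output path (`.vcf`).
#' @param sample_name Value for the `##source` sample tag.
#' @return `path`, invisibly.
#' @export
write_snps_vcf <- function(snps, path, sample_name = "sample") {
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##source=recombiscan %s (%s)", packageVersion("recombiscan"),
            sample_name),
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"MAPQ-passing depth\">",
    "##INFO=<ID=AD,Number=2,Type=Integer,Description=\"Major,second allele read counts\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  records <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tDP=%d;AD=%d,%d",
                     snps$scaffold, snps$pos, snps$allele1, snps$allele2,
                     snps$depth, snps$count1, snps$count2)
  writeLines(c(header, records), path)
  invisible(path)
}

#' Write a tibble as TSV
#' @param x A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv_file <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv_file()]
#' @param path Input path.
#' @return A tibble.
#' @export
read_tsv_file <- function(path) {
  as_tibble(read.delim(path, sep = "\t", stringsAsFactors = FALSE))
}

#' Write every artifact of a simulated trio to a directory
#'
#' Emits the reference FASTA, the GFF3 gene annotation, the ground-truth SNP
#' table (TSV), and per sample: reads as FASTQ, alignments as SAM, and the
#' per-read truth table (read id, source label, breakpoint) as TSV. Identical
#' configurations produce byte-identical files.
#'
#' @param trio Output of [simulate_trio()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_sim_outputs <- function(trio, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  lens <- setNames(nchar(trio$reference$sequences),
                   names(trio$reference$sequences))
  paths <- c(
    reference = write_fasta(trio$reference$sequences,
                            file.path(dir, "reference.fasta")),
    genes = write_gff3(trio$reference$genes, file.path(dir, "genes.gff3")),
    snp_table = write_tsv_file(trio$haplotypes$snp_table,
                               file.path(dir, "snp_table.tsv"))
  )
  for (nm in names(trio$samples)) {
    reads <- trio$samples[[nm]]$reads
    paths[paste0(nm, "_sam")] <-
      write_sam(reads[c("read_id", "scaffold", "pos", "seq", "mapq")], lens,
                file.path(dir, paste0(nm, ".sam")))
    paths[paste0(nm, "_fastq")] <-
      write_fastq(reads, file.path(dir, paste0(nm, ".fastq")))
    paths[paste0(nm, "_truth")] <- write_tsv_file(
      reads[c("read_id", "scaffold", "pos", "molecule_id", "source",
              "left_parent", "breakpoint")],
      file.path(dir, paste0(nm, ".truth.tsv"))
    )
  }
  invisible(paths)
}
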
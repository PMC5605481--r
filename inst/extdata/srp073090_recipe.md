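# Reproducing the real-data summary table (optional, not desk scale)

The original study design can be re-analysed end to end with this package,
but the inputs are multi-gigabyte and alignment takes hours, so the recipe is
documented rather than executed in the test suite.

Inputs:

1. Reads: NCBI SRA study **SRP073090** — whole-genome PCR-free Illumina
   HiSeq 2500 paired-end libraries (up to 250 cycles) of the two homokaryons
   *BS05* and *BS17* and the heterokaryon *BS05 x BS17*.
2. Reference: *Termitomyces* sp. *J132* draft genome, GigaDB dataset 100056
   (http://gigadb.org/dataset/100056), with its gene annotation (GFF3) for
   the enrichment stage.

Steps:

1. Trim adapters (cutadapt) and align each sample to the J132 reference with
   Bowtie 2 in local alignment mode; coordinate-sort and index the BAMs
   (alignment is outside this package's scope — it consumes aligned reads).
2. In R:

       library(recombiscan)
       scan <- run_scan(
         heterokaryon = "BS05xBS17.bam",
         homokaryon1  = "BS05.bam",
         homokaryon2  = "BS17.bam",
         scaffold_lengths = lens,      # from the FASTA index
         annotation = "j132_genes.gff3",
         mapq_min = 10, min_depth = 10, major_frac = 0.90, max_diff = 0.20,
         k = 5, window_policy = "leading"
       )
       scan$table2
       write_report(scan, "report.json")

Expected outcome: roughly 60-75 thousand heterozygous SNPs per sample; the
filtered heterokaryon column of the summary table should show about 5% of
phased reads (those covering >= 5 heterozygous SNPs) as recombinant
(published value 5.04%, from 21,336 of 422,959 reads), with homokaryon
recombinant fractions near 19-20% before cross-sample filtering, and a less
than twofold enrichment of recombinants in genic regions.
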
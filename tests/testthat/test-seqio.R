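test_that("load_reference parses FASTA + BED12 and orders minus-strand exons", {
  dir <- withr::local_tempdir()
  tiny <- write_tiny_reference(dir)
  ref <- load_reference(tiny$fasta, tiny$bed)

  expect_length(ref$genome, 2L)
  expect_identical(nchar(ref$genome[["chrA"]]), 60L)
  expect_identical(unique(ref$genes$gene_id), "geneM")

  # minus strand: transcription order runs from the largest coordinates
  ex <- ref$genes[order(ref$genes$exon_rank), ]
  expect_identical(ex$start, c(45L, 25L, 5L))
  expect_identical(ex$end, c(55L, 35L, 15L))
  tss <- transcript_tss(ref$genes)
  expect_identical(tss$tss, 54L)

  # exon + intron lengths tile the gene span
  introns <- enumerate_introns(ref$genes)
  span <- max(ref$genes$end) - min(ref$genes$start)
  expect_identical(sum(ref$genes$end - ref$genes$start) +
                     sum(introns$length), span)
})

test_that("a gene referencing an absent contig is a hard error", {
  dir <- withr::local_tempdir()
  tiny <- write_tiny_reference(dir)
  bad <- file.path(dir, "bad.bed")
  writeLines(paste("chrZ", 0, 30, "ghost", 0, "+", 0, 30, "0", 1,
                   "30", "0", sep = "\t"), bad)
  expect_error(load_reference(tiny$fasta, bad), "ghost")
})

test_that("GTF exons are grouped by transcript and ranked", {
  dir <- withr::local_tempdir()
  fa <- file.path(dir, "g.fa")
  writeLines(c(">c1", strrep("ACGT", 50)), fa)
  gtf <- file.path(dir, "g.gtf")
  attrs <- 'gene_id "g1"; transcript_id "g1.t1";'
  writeLines(c(
    paste("c1", "test", "exon", 1, 40, ".", "+", ".", attrs, sep = "\t"),
    paste("c1", "test", "exon", 101, 140, ".", "+", ".", attrs, sep = "\t")),
    gtf)
  ref <- load_reference(fa, gtf)
  expect_identical(nrow(ref$genes), 2L)
  expect_identical(ref$genes$start, c(0L, 100L))  # 1-based GTF -> 0-based
  expect_identical(ref$genes$exon_rank, c(1L, 2L))
})

test_that("reverse_complement inverts the printed mutagenesis primers", {
  expect_identical(reverse_complement("gttgctcattaacggatatcttaacg"),
                   "cgttaagatatccgttaatgagcaac")
  expect_identical(reverse_complement("gtacgtaaccatttcgggttttttccttaaatagtg"),
                   "cactatttaaggaaaaaacccgaaatggttacgtac")
  expect_identical(reverse_complement("GGATCC"), "GGATCC")  # palindrome
  expect_error(reverse_complement("ACGU"), "non-nucleotide")
})

test_that("reverse_complement is an involution and matches Biostrings", {
  withr::with_seed(101, {
    for (i in 1:25) {
      s <- paste(sample(c("A", "C", "G", "T", "N"), sample(1:80, 1),
                        replace = TRUE), collapse = "")
      expect_identical(reverse_complement(reverse_complement(s)), s)
      expect_identical(reverse_complement(s), oracle_revcomp(s))
    }
  })
})

test_that("mutagenesis primer pairs verify as exact reverse complements", {
  f1 <- primer("3'ssmF", "gttgctcattaacggatatcttaacg")
  r1 <- primer("3'ssmR", "cgttaagatatccgttaatgagcaac")
  f2 <- primer("DoubleF", "gtacgtaaccatttcgggttttttccttaaatagtg")
  r2 <- primer("DoubleR", "cactatttaaggaaaaaacccgaaatggttacgtac")
  expect_true(verify_primer_pair(f1, r1))
  expect_true(verify_primer_pair(f2, r2))
  expect_false(verify_primer_pair(f1, r2))
})

test_that("find_motif reports all overlapping 0-based offsets", {
  expect_identical(find_motif("AATAAA", "AATAAA"), 0L)
  expect_identical(find_motif("ACGT", "AATAAA"), integer(0))
  s <- "TTAATAAATAAATT"
  expect_identical(find_motif(s, "AATAAA"), oracle_find_motif(s, "AATAAA"))
  # overlapping run
  s2 <- "AATAAATAAATAAA"
  expect_identical(find_motif(s2, "AATAAA"), oracle_find_motif(s2, "AATAAA"))
  expect_true(length(find_motif(s2, "AATAAA")) >
                length(find_motif(s2, "AATAAA", allow_overlap = FALSE)))
})

test_that("find_motif agrees with its strand reflection", {
  withr::with_seed(202, {
    for (i in 1:20) {
      s <- paste(sample(c("A", "C", "G", "T"), 120, replace = TRUE),
                 collapse = "")
      m <- paste(sample(c("A", "C", "G", "T"), 4, replace = TRUE),
                 collapse = "")
      fwd <- find_motif(s, m)
      rev <- find_motif(reverse_complement(s), reverse_complement(m))
      reflected <- sort(nchar(s) - nchar(m) - rev)
      expect_identical(fwd, as.integer(reflected))
    }
  })
})

test_that("Ns never match a motif", {
  expect_identical(find_motif("AANAAA", "AATAAA"), integer(0))
  expect_identical(find_motif("NNNNNN", "AATAAA"), integer(0))
})
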
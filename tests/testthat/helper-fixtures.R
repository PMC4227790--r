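# Shared fixtures. Everything is generated in code at test time; the
# miniature geometry keeps whole-genome brute-force comparisons fast while
# exercising every positional rule (the screen's distance parameters scale
# with it).

# Screen parameters for the miniature geometry: every rule keeps its
# structure (inclusive stage-1 bounds, strict refinement bound, unchanged
# consensus-value thresholds), only the distances shrink.
mini_params <- function() {
  screen_params(min_intron_len = 100L, max_5ss_dist = 100L,
                refined_max_5ss_dist = 80L)
}

mini_config <- function(n_genes = 10L, ...) {
  args <- list(n_genes = n_genes, n_exons = 3L,
               exon_len = c(52L, 72L),
               host_intron_len = c(130L, 170L),
               other_intron_len = c(45L, 80L),
               pa_offset = c(72L, 78L),
               n_cryptic_sites = 1L,
               site_dists = c(5L, 38L),
               flank = 20L)
  over <- list(...)
  args[names(over)] <- over
  do.call(synthetic_config, args)
}

# Default-scale toy reference shared across test files (generated once).
.fixture_cache <- new.env(parent = emptyenv())
toy_default <- function(seed = 11L, n_cryptic_sites = 3L) {
  key <- paste0("toy_", seed, "_", n_cryptic_sites)
  if (is.null(.fixture_cache[[key]])) {
    cfg <- synthetic_config(n_genes = 2L, n_cryptic_sites = n_cryptic_sites)
    .fixture_cache[[key]] <- generate_toy_genome(cfg, seed = seed)
  }
  .fixture_cache[[key]]
}

# A tiny hand-written reference: two contigs, one 3-exon minus-strand gene
# on a 60 nt contig, written to FASTA + BED12 on disk.
write_tiny_reference <- function(dir) {
  ctg1 <- paste(rep("ACGT", 15), collapse = "")        # 60 nt
  ctg2 <- strrep("G", 40)
  fa <- file.path(dir, "tiny.fa")
  writeLines(c(">chrA", ctg1, ">chrB", ctg2), fa)
  # BED12: 3 blocks of 10 nt at genomic [5,15) [25,35) [45,55), minus strand
  bed <- file.path(dir, "tiny.bed")
  writeLines(paste("chrA", 5, 55, "geneM", 0, "-", 5, 55, "0", 3,
                   "10,10,10", "0,20,40", sep = "\t"), bed)
  list(fasta = fa, bed = bed, ctg1 = ctg1, ctg2 = ctg2)
}

# Normalise tibbles for round-trip comparison after TSV re-import (column
# classes may legitimately widen, e.g. integer -> double).
normalize_df <- function(d) {
  d <- as.data.frame(d)
  for (j in seq_along(d)) {
    if (is.numeric(d[[j]])) d[[j]] <- as.numeric(d[[j]])
  }
  d[order(names(d))]
}
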
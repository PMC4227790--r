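# Exon tibble builder for hand-laid-out genes.
make_gene <- function(starts, ends, strand = "+", contig = "c1",
                      gene_id = "g1") {
  n <- length(starts)
  rank <- if (strand == "+") seq_len(n) else rev(seq_len(n))
  tibble::tibble(gene_id = gene_id, transcript_id = paste0(gene_id, ".t1"),
                 contig = contig, strand = strand,
                 start = as.integer(starts), end = as.integer(ends),
                 exon_rank = rank)[order(rank), ]
}

test_that("enumerate_introns computes ordinals, lengths and distances", {
  expect_identical(nrow(enumerate_introns(make_gene(0, 100))), 0L)

  g <- make_gene(c(0, 1300, 2000), c(100, 1400, 2100))
  introns <- enumerate_introns(g)
  expect_identical(introns$ordinal, c(1L, 2L))
  expect_identical(introns$length, c(1200L, 600L))
  expect_identical(introns$five_ss, c(100L, 1400L))
  expect_identical(introns$tss_offset, c(100L, 200L))

  # same intervals on the minus strand: ordinals reverse relative to
  # genomic order, lengths swap
  gm <- make_gene(c(0, 1300, 2000), c(100, 1400, 2100), strand = "-")
  im <- enumerate_introns(gm)
  expect_identical(im$ordinal, c(1L, 2L))
  expect_identical(im$length, c(600L, 1200L))
  expect_identical(im$five_ss, c(1999L, 1299L))
})

test_that("intronic signals are found with transcript-relative distances", {
  withr::with_seed(33, {
    bg <- paste(sample(c("C", "G", "T"), 2100, replace = TRUE), collapse = "")
  })
  g <- make_gene(c(0, 1300, 2000), c(100, 1400, 2100))
  seq <- bg
  substr(seq, 100 + 800 + 1, 100 + 806) <- "AATAAA"  # 800 nt into intron 1
  genome <- c(c1 = seq)
  hits <- find_intronic_polya_signals(g, genome)
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$dist_from_5ss, 800L)
  expect_identical(hits$dist_from_tss, 900L)
  expect_identical(hits$ordinal, 1L)
  expect_true(is.na(hits$passes_stage1))

  # exonic occurrence only -> nothing
  seq2 <- bg
  substr(seq2, 11, 16) <- "AATAAA"
  expect_identical(nrow(find_intronic_polya_signals(g, c(c1 = seq2))), 0L)

  # a hexamer straddling the 5' splice site is not intronic
  seq3 <- bg
  substr(seq3, 98, 103) <- "AATAAA"  # covers exon offsets 97..99 + intron 0..2
  h3 <- find_intronic_polya_signals(g, c(c1 = seq3))
  expect_false(any(h3$dist_from_5ss < 3L))
})

test_that("positional filters follow inclusive 5kb/1kb and strict 500bp rules", {
  base <- tibble::tibble(
    gene_id = "g", transcript_id = "t", ordinal = 1L, contig = "c",
    strand = "+", intron_start = 0L, intron_end = 1200L,
    intron_length = 1200L, five_ss = 0L, three_ss = 1200L,
    hexamer = "AATAAA", signal_start = 0L,
    dist_from_5ss = 800L, dist_from_tss = 900L,
    passes_stage1 = NA, passes_refinement = NA)
  f <- function(h) filter_promoter_proximal(h)

  r <- f(base)
  expect_true(r$passes_stage1)        # within all inclusive bounds
  expect_false(r$passes_refinement)   # 800 >= 500

  expect_true(f(dplyr::mutate(base, dist_from_5ss = 499L))$passes_refinement)
  expect_false(f(dplyr::mutate(base, dist_from_5ss = 500L))$passes_refinement)

  expect_true(f(dplyr::mutate(base, dist_from_tss = 5000L))$passes_stage1)
  expect_false(f(dplyr::mutate(base, dist_from_tss = 5001L))$passes_stage1)

  expect_true(f(dplyr::mutate(base, dist_from_5ss = 1000L))$passes_stage1)
  expect_false(f(dplyr::mutate(base, dist_from_5ss = 1001L))$passes_stage1)

  expect_false(f(dplyr::mutate(base, ordinal = 3L))$passes_stage1)
  expect_false(f(dplyr::mutate(base, intron_length = 999L))$passes_stage1)
  expect_true(f(dplyr::mutate(base, intron_length = 1000L))$passes_stage1)
})

test_that("shrinking any bound never admits new hits and refinement is nested", {
  toy <- toy_default()
  hits <- find_intronic_polya_signals(toy$genes, toy$genome) |>
    filter_promoter_proximal()
  expect_true(all(which(hits$passes_refinement) %in%
                    which(hits$passes_stage1)))
  n_pass <- function(p) {
    sum(filter_promoter_proximal(hits, p)$passes_stage1)
  }
  base <- screen_params()
  for (p in list(screen_params(max_tss_dist = 400L),
                 screen_params(max_5ss_dist = 200L,
                               refined_max_5ss_dist = 200L),
                 screen_params(min_intron_len = 2000L),
                 screen_params(allowed_intron_ordinals = 1L))) {
    expect_lte(n_pass(p), n_pass(base))
  }
})

test_that("hit sets match the brute-force oracle on random synthetic genes", {
  params <- mini_params()
  toy <- generate_toy_genome(mini_config(20L, scrub_spurious = FALSE),
                             seed = 77, params = params)
  prod <- find_intronic_polya_signals(toy$genes, toy$genome, params) |>
    filter_promoter_proximal(params)
  orc <- oracle_polya_hits(toy$genes, toy$genome, params)
  cols <- c("transcript_id", "ordinal", "signal_start", "dist_from_5ss",
            "dist_from_tss", "passes_stage1", "passes_refinement")
  prod <- as.data.frame(prod[cols])
  prod <- prod[do.call(order, prod), ]
  orc <- as.data.frame(orc[cols])
  orc <- orc[do.call(order, orc), ]
  rownames(prod) <- rownames(orc) <- NULL
  expect_identical(prod, orc)
  expect_gt(nrow(prod), 0L)
})
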
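# One fully planted synthetic gene plus its screen calls, shared below.
tx_fixture <- function() {
  toy <- toy_default()
  hits <- find_intronic_polya_signals(toy$genes, toy$genome) |>
    filter_promoter_proximal()
  acc <- call_cryptic_acceptors(hits, toy$genes, toy$genome)
  g1 <- toy$genes[toy$genes$gene_id == "gene01", ]
  list(toy = toy, genes = g1,
       hit = hits[hits$gene_id == "gene01" & hits$passes_refinement, ][1, ],
       acc = acc[acc$gene_id == "gene01", ])
}

test_that("transcript kinds obey the segment and length arithmetic", {
  fx <- tx_fixture()
  toy <- fx$toy
  params <- screen_params()

  mrna <- build_transcript(fx$genes, toy$genome, "mRNA")
  exon_len <- sum(fx$genes$end - fx$genes$start)
  expect_identical(nchar(mrna$seq), exon_len + params$polya_tail_len)
  expect_true(mrna$polyadenylated)

  pcpa <- build_transcript(fx$genes, toy$genome, "PCPA", pa_hit = fx$hit)
  e1 <- fx$genes$end[fx$genes$exon_rank == 1] -
    fx$genes$start[fx$genes$exon_rank == 1]
  expect_identical(nchar(pcpa$seq),
                   e1 + fx$hit$dist_from_5ss + 6L + params$cleavage_offset +
                     params$polya_tail_len)

  # CSPP is PCPA minus the excised 5'ss-to-junction interval
  a1 <- fx$acc[fx$acc$rank == 1L, ]
  cspp <- build_transcript(fx$genes, toy$genome, "CSPP", pa_hit = fx$hit,
                           acceptor = a1)
  expect_identical(nchar(pcpa$seq) - nchar(cspp$seq), a1$junction_offset)

  rt <- build_transcript(fx$genes, toy$genome, "read-through",
                         pa_hit = fx$hit)
  expect_false(rt$polyadenylated)
  expect_identical(rt$tail_len, 0L)
  expect_gt(nchar(rt$seq), nchar(pcpa$seq) - params$polya_tail_len)

  # the hexamer lies upstream of the cleavage position inside the terminus
  body <- substr(pcpa$seq, 1, nchar(pcpa$seq) - params$polya_tail_len)
  expect_identical(substr(body, nchar(body) - params$cleavage_offset - 5L,
                          nchar(body) - params$cleavage_offset),
                   "AATAAA")
})

test_that("CSPP construction demands a qualifying acceptor upstream of cleavage", {
  fx <- tx_fixture()
  expect_error(build_transcript(fx$genes, fx$toy$genome, "CSPP",
                                pa_hit = fx$hit),
               "acceptor")
  bad <- fx$acc[fx$acc$rank == 1L, ]
  bad$junction_offset <- fx$hit$dist_from_5ss + 6L + 15L + 10L
  expect_error(build_transcript(fx$genes, fx$toy$genome, "CSPP",
                                pa_hit = fx$hit, acceptor = bad),
               "downstream")
})

test_that("cis-element extraction enforces the 157/51 pad geometry", {
  fx <- tx_fixture()
  el <- extract_cis_element(fx$genes, fx$toy$genome, fx$hit)
  expect_identical(nchar(el$seq), 157L + 6L + 51L)
  expect_identical(substr(el$seq, 158, 163), "AATAAA")

  bare <- extract_cis_element(fx$genes, fx$toy$genome, fx$hit,
                              upstream_pad = 0, downstream_pad = 0)
  expect_identical(bare$seq, "AATAAA")

  near <- fx$hit
  near$dist_from_5ss <- 100L
  expect_error(extract_cis_element(fx$genes, fx$toy$genome, near),
               "boundary")
})

test_that("reporter insertion places the element and neutralization kills only the vector pA", {
  fx <- tx_fixture()
  el <- extract_cis_element(fx$genes, fx$toy$genome, fx$hit)
  rep0 <- example_reporter(seed = 3)

  # intron insertion: the element's signal is rediscovered as intronic
  rin <- insert_cis_element(rep0, el, site = "intron", at = 150L)
  model <- reporter_gene_model(rin)
  hits <- find_intronic_polya_signals(model$genes, model$genome) |>
    filter_promoter_proximal()
  intronic <- hits[hits$hexamer == "AATAAA" & hits$ordinal == 1L, ]
  expect_identical(intronic$dist_from_5ss, 150L + 157L)
  expect_true(intronic$passes_refinement)

  # the same element behaves as in the endogenous gene: its rank-1 cryptic
  # site is re-called at the same distance from the signal
  acc <- call_cryptic_acceptors(hits, model$genes, model$genome)
  expect_true(30L %in% acc$dist_to_polya)

  # 3' exon insertion with vector-pA neutralization
  rex <- insert_cis_element(rep0, el, site = "three_prime_exon",
                            neutralize_vector_pa = TRUE)
  expect_identical(find_motif(rex$segments[["vector_pa"]], "AATAAA"),
                   integer(0))
  expect_true(grepl("GGATCC", rex$segments[["vector_pa"]], ignore.case = TRUE))
  expect_length(find_motif(rex$segments[["three_prime_exon"]], "AATAAA"), 1L)

  # neutralizing an AATAAA-free segment is a no-op
  expect_identical(pcpascreen:::neutralize_polya("CCGGTT"), "CCGGTT")
  expect_identical(pcpascreen:::neutralize_polya("xxaataaayy"), "xxggatccyy")
})

test_that("targeted mutations silence elements minimally and compose", {
  toy <- toy_default()
  g1 <- "gene01"

  # poly(A) mutation removes the signal entirely
  pam <- apply_mutation(toy$genome, toy$genes, "polya_signal", gene_id = g1)
  h <- find_intronic_polya_signals(toy$genes[toy$genes$gene_id == g1, ],
                                   pam$genome)
  expect_identical(nrow(h), 0L)
  expect_identical(pam$edits$alt, "GGATCC")

  # edits touch at most motif-length bases
  d <- mapply(function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]]),
              toy$genome, pam$genome)
  expect_lte(sum(d), 6L)

  # donor mutation: PCPA still builds, CSPP no longer can
  ssm <- apply_mutation(toy$genome, toy$genes, "five_ss", gene_id = g1)
  pool <- generate_transcript_pool(toy$genes, ssm$genome, kinds = "PCPA",
                                   gene_id = g1)
  expect_identical(pool$kind, "PCPA")
  expect_error(generate_transcript_pool(toy$genes, ssm$genome,
                                        kinds = c("PCPA", "CSPP"),
                                        gene_id = g1),
               "donor")

  # masking sites 1 and 2 exposes site 3
  m1 <- apply_mutation(toy$genome, toy$genes, "cryptic_3ss", site_index = 1,
                       gene_id = g1)
  m2 <- apply_mutation(m1$genome, toy$genes, "cryptic_3ss", site_index = 1,
                       gene_id = g1)
  hits <- find_intronic_polya_signals(toy$genes[toy$genes$gene_id == g1, ],
                                      m2$genome) |>
    filter_promoter_proximal()
  acc <- call_cryptic_acceptors(hits, toy$genes[toy$genes$gene_id == g1, ],
                                m2$genome)
  expect_identical(acc$dist_to_polya[acc$rank == 1L], 260L)

  # absent target
  expect_error(apply_mutation(m2$genome, toy$genes, "cryptic_3ss",
                              site_index = 3, gene_id = g1),
               "rank")
})
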
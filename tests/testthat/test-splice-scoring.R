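toy_matrix <- function() {
  freq_matrix("toy2", rbind(c(0.7, 0.1, 0.1, 0.1),
                            c(0.4, 0.3, 0.2, 0.1)) |>
                `colnames<-`(c("A", "C", "G", "T")))
}

test_that("consensus value follows the normalised frequency-sum formula", {
  m <- toy_matrix()
  # S = 0.7 + 0.2, Smin = 0.1 + 0.1, Smax = 0.7 + 0.4
  expect_equal(consensus_value("AG", m), 100 * (0.9 - 0.2) / (1.1 - 0.2))
  expect_equal(consensus_value("AA", m), 100)
  expect_equal(consensus_value(c("CT", "GT"), m),
               c(100 * (0.1 + 0.1 - 0.2) / 0.9, 100 * (0.1 + 0.1 - 0.2) / 0.9))
  expect_error(consensus_value("A", m), "width")
  expect_warning(v <- consensus_value("AN", m), "N")
  expect_true(is.na(v))
})

test_that("shipped matrices score consensus 100, anti-consensus 0, and agree with the oracle", {
  for (m in default_matrices()) {
    expect_equal(consensus_value(consensus_window(m), m), 100)
    expect_equal(consensus_value(anti_consensus_window(m), m), 0)
    withr::with_seed(7, {
      wins <- vapply(1:50, function(i)
        paste(sample(c("A", "C", "G", "T"), m$width, replace = TRUE),
              collapse = ""), character(1))
    })
    cv <- consensus_value(wins, m)
    expect_true(all(cv >= 0 & cv <= 100))
    expect_equal(cv, vapply(wins, oracle_cv, numeric(1), m = m,
                            USE.NAMES = FALSE))
  }
})

test_that("raising the observed base's frequency never lowers the cv", {
  m <- default_matrices()$branch
  withr::with_seed(13, {
    for (i in 1:30) {
      w <- paste(sample(c("A", "C", "G", "T"), m$width, replace = TRUE),
                 collapse = "")
      p <- sample(m$width, 1)
      obs <- substr(w, p, p)
      others <- setdiff(colnames(m$freqs), obs)
      donor <- others[which.max(m$freqs[p, others])]
      delta <- min(0.05, m$freqs[p, donor])
      f2 <- m$freqs
      f2[p, obs] <- f2[p, obs] + delta
      f2[p, donor] <- f2[p, donor] - delta
      m2 <- freq_matrix("pert", f2)
      expect_gte(consensus_value(w, m2) + 1e-9, consensus_value(w, m))
    }
  })
})

test_that("cv is invariant under joint position permutation", {
  m <- default_matrices()$branch
  withr::with_seed(17, {
    for (i in 1:10) {
      w <- paste(sample(c("A", "C", "G", "T"), m$width, replace = TRUE),
                 collapse = "")
      perm <- sample(m$width)
      m2 <- freq_matrix("perm", m$freqs[perm, , drop = FALSE])
      w2 <- paste(strsplit(w, "")[[1]][perm], collapse = "")
      expect_equal(consensus_value(w2, m2), consensus_value(w, m))
    }
  })
})

test_that("a planted consensus pair is called once and dies with its AG", {
  mats <- default_matrices()
  region <- strrep("T", 400)
  bw <- consensus_window(mats$branch)
  aw <- consensus_window(mats$acceptor)
  j <- 300L
  substr(region, j - 13 + 1, j + 1) <- aw            # junction at offset 300
  substr(region, j - 25 - 7 + 1, j - 25) <- bw       # branch end 25 nt upstream
  sites <- scan_cryptic_acceptors(region, mats)
  expect_identical(nrow(sites), 1L)
  expect_equal(sites$acceptor_cv, 100)
  expect_equal(sites$branch_cv, 100)
  expect_identical(sites$junction_offset, j)

  # destroying the invariant AG (the 3'ss-1m edit) silences the site
  mut <- region
  substr(mut, j, j) <- "T"   # the G of the AG, 1-based position j
  expect_identical(nrow(scan_cryptic_acceptors(mut, mats)), 0L)
})

test_that("scan results equal the exhaustive nested-loop oracle", {
  mats <- default_matrices()
  params <- screen_params()
  withr::with_seed(23, {
    for (i in 1:6) {
      region <- paste(sample(c("A", "C", "G", "T"), 2000, replace = TRUE),
                      collapse = "")
      prod <- scan_cryptic_acceptors(region, mats, params)
      orc <- oracle_scan(region, mats, params)
      expect_identical(nrow(prod), length(orc))
      if (length(orc)) {
        orc <- do.call(rbind, orc)
        expect_identical(prod$acceptor_start, as.integer(orc$acceptor_start))
        expect_identical(prod$branch_start, as.integer(orc$branch_start))
        expect_equal(prod$acceptor_cv, orc$acceptor_cv)
        expect_equal(prod$branch_cv, orc$branch_cv)
      }
    }
  })
})

test_that("thresholds act as pure filters", {
  mats <- default_matrices()
  withr::with_seed(29, {
    region <- paste(sample(c("A", "C", "G", "T"), 1500, replace = TRUE),
                    collapse = "")
  })
  loose <- scan_cryptic_acceptors(region, mats,
                                  screen_params(acceptor_cv_threshold = 30,
                                                branch_cv_threshold = 40))
  tight <- scan_cryptic_acceptors(region, mats,
                                  screen_params(acceptor_cv_threshold = 45,
                                                branch_cv_threshold = 55))
  expect_true(all(tight$junction_offset %in% loose$junction_offset))
  expect_lte(nrow(tight), nrow(loose))
})

test_that("sites rank by distance to the signal and the cascade promotes", {
  toy <- toy_default()
  res <- run_screen(toy$genome, toy$genes)
  acc <- res$acceptors |> dplyr::filter(gene_id == "gene01")
  expect_identical(acc$dist_to_polya[order(acc$rank)], c(30L, 120L, 260L))

  # single site trivially ranks 1
  one <- rank_cryptic_sites(acc[acc$rank == 2L, ])
  expect_identical(one$rank, 1L)

  # masking the rank-1 AG re-ranks the former rank-2 site first
  m1 <- apply_mutation(toy$genome, toy$genes, "cryptic_3ss", site_index = 1,
                       gene_id = "gene01")
  hits <- find_intronic_polya_signals(toy$genes, m1$genome) |>
    filter_promoter_proximal()
  acc2 <- call_cryptic_acceptors(hits, toy$genes, m1$genome) |>
    dplyr::filter(gene_id == "gene01")
  expect_identical(acc2$dist_to_polya[acc2$rank == 1L], 120L)
})
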
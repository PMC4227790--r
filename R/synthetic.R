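#' Configuration for the synthetic-genome generator
#'
#' Defines the study conditions every planted gene emulates: multi-exon
#' genes on alternating strands, a poly(A) hexamer planted at a controlled
#' distance from the 5' splice site of a 1 kb-class promoter-proximal
#' intron, and branch/acceptor motif pairs sampled into controlled
#' consensus-value bands upstream of the signal. Decoy modes plant elements
#' that fail the positional rules instead.
#'
#' @param n_genes Number of genes (one contig each).
#' @param n_exons Exons per gene.
#' @param exon_len Exon-length range (nt).
#' @param host_intron_len Length range of the intron hosting the planted
#'   signal (default comfortably above the 1 kb minimum).
#' @param other_intron_len Length range of the remaining introns.
#' @param pa_intron Intron ordinal hosting the planted signal.
#' @param pa_offset Range of planted hexamer distances from the 5' splice
#'   site; the default passes the strict < 500 bp refinement.
#' @param n_cryptic_sites Cryptic branch/acceptor pairs planted per gene.
#' @param site_dists Planted distances (nt) from each cryptic junction to
#'   the hexamer start, nearest first; the first `n_cryptic_sites` are used.
#' @param acceptor_cv_band,branch_cv_band Consensus-value bands the planted
#'   windows are sampled into (defaults above the 39.41/50.16 thresholds).
#' @param branch_gap nt from the planted branch 7-mer's end to its junction
#'   (must lie inside the screen's spacing window).
#' @param decoy `"none"` (plant passing elements), `"deep_intron"` (signal
#'   in the last intron, failing the ordinal rule) or `"far"` (signal
#'   1500 nt from the 5' splice site, failing the 1 kb rule).
#' @param background Base-composition weights for background sequence.
#' @param flank Flanking nt on each side of the gene.
#' @param scrub_spurious Remove unplanted hexamers and spurious
#'   above-threshold acceptor registers from the background.
#' @return A `synthetic_config` object.
#' @export
synthetic_config <- function(n_genes = 10L, n_exons = 3L,
                             exon_len = c(150L, 250L),
                             host_intron_len = c(1100L, 1600L),
                             other_intron_len = c(400L, 800L),
                             pa_intron = 1L,
                             pa_offset = c(300L, 420L),
                             n_cryptic_sites = 1L,
                             site_dists = c(30L, 120L, 260L),
                             acceptor_cv_band = c(65, 95),
                             branch_cv_band = c(65, 95),
                             branch_gap = 25L,
                             decoy = c("none", "deep_intron", "far"),
                             background = c(A = 0.25, C = 0.25,
                                            G = 0.25, T = 0.25),
                             flank = 100L,
                             scrub_spurious = TRUE) {
  decoy <- match.arg(decoy)
  stopifnot(n_genes >= 1L, n_exons >= 2L,
            length(exon_len) == 2L, exon_len[1] <= exon_len[2],
            length(host_intron_len) == 2L,
            host_intron_len[1] <= host_intron_len[2],
            length(other_intron_len) == 2L,
            other_intron_len[1] <= other_intron_len[2],
            length(pa_offset) == 2L, pa_offset[1] <= pa_offset[2],
            n_cryptic_sites >= 0L, n_cryptic_sites <= length(site_dists),
            branch_gap >= 0L, flank >= 0L,
            setequal(names(background), c("A", "C", "G", "T")),
            all(background > 0))
  if (decoy == "deep_intron" && n_exons < 4L) {
    abort("deep_intron decoys need at least 4 exons (a third intron)")
  }
  structure(list(n_genes = as.integer(n_genes), n_exons = as.integer(n_exons),
                 exon_len = as.integer(exon_len),
                 host_intron_len = as.integer(host_intron_len),
                 other_intron_len = as.integer(other_intron_len),
                 pa_intron = as.integer(pa_intron),
                 pa_offset = as.integer(pa_offset),
                 n_cryptic_sites = as.integer(n_cryptic_sites),
                 site_dists = as.integer(sort(site_dists)),
                 acceptor_cv_band = acceptor_cv_band,
                 branch_cv_band = branch_cv_band,
                 branch_gap = as.integer(branch_gap),
                 decoy = decoy,
                 background = background[c("A", "C", "G", "T")],
                 flank = as.integer(flank),
                 scrub_spurious = isTRUE(scrub_spurious)),
            class = "synthetic_config")
}

#' Sample a motif window with a prescribed consensus value
#'
#' Randomised hill climbing over single-base substitutions at free
#' positions: starting from a random window (invariant bases fixed), the
#' sampler proposes substitutions and keeps those that move the consensus
#' value toward the band, restarting periodically. Deterministic under
#' `seed`; with `seed = NULL` it draws from the current RNG stream.
#'
#' @param matrix A `freq_matrix`.
#' @param cv_band Numeric length-2 target interval within `[0, 100]`.
#' @param seed Optional integer seed.
#' @param exclude_motifs Motifs the returned window must not contain (used
#'   to keep poly(A) hexamers out of planted splice windows).
#' @param max_tries Proposal budget before giving up.
#' @return A window string whose [consensus_value()] lies in `cv_band`.
#' @export
sample_motif_with_cv <- function(matrix, cv_band, seed = NULL,
                                 exclude_motifs = character(0),
                                 max_tries = 5000L) {
  stopifnot(length(cv_band) == 2L, cv_band[1] <= cv_band[2])
  if (cv_band[1] < 0 || cv_band[2] > 100) {
    abort("cv_band must lie within [0, 100]")
  }
  req_pos <- as.integer(names(matrix$required_bases))
  free_pos <- setdiff(seq_len(matrix$width), req_pos)
  # achievable range given the invariant bases
  fmin <- apply(matrix$freqs, 1, min)
  fmax <- apply(matrix$freqs, 1, max)
  req_f <- if (length(req_pos))
    matrix$freqs[cbind(req_pos, match(matrix$required_bases,
                                      colnames(matrix$freqs)))] else numeric(0)
  smin <- sum(fmin); smax <- sum(fmax)
  lo_ach <- 100 * (sum(req_f) + sum(fmin[free_pos]) - smin) / (smax - smin)
  hi_ach <- 100 * (sum(req_f) + sum(fmax[free_pos]) - smin) / (smax - smin)
  if (cv_band[2] < lo_ach - 1e-9 || cv_band[1] > hi_ach + 1e-9) {
    abort(sprintf("cv band [%g, %g] unreachable (achievable [%.2f, %.2f])",
                  cv_band[1], cv_band[2], lo_ach, hi_ach))
  }
  run <- function() {
    bases <- c("A", "C", "G", "T")
    fresh <- function() {
      w <- sample(bases, matrix$width, replace = TRUE)
      w[req_pos] <- matrix$required_bases
      w
    }
    band_dist <- function(cv) {
      if (cv >= cv_band[1] && cv <= cv_band[2]) 0 else
        min(abs(cv - cv_band[1]), abs(cv - cv_band[2]))
    }
    ok_window <- function(w) {
      s <- paste(w, collapse = "")
      if (length(exclude_motifs) &&
          any(vapply(exclude_motifs,
                     function(m) length(find_motif(s, m)) > 0L, logical(1)))) {
        return(NULL)
      }
      s
    }
    w <- fresh()
    cv <- consensus_value(paste(w, collapse = ""), matrix)
    stall <- 0L
    for (i in seq_len(max_tries)) {
      if (band_dist(cv) == 0) {
        s <- ok_window(w)
        if (!is.null(s)) return(s)
        w <- fresh()
        cv <- consensus_value(paste(w, collapse = ""), matrix)
        next
      }
      p <- if (length(free_pos) == 1L) free_pos else sample(free_pos, 1L)
      b <- sample(bases, 1L)
      w2 <- w; w2[p] <- b
      cv2 <- consensus_value(paste(w2, collapse = ""), matrix)
      if (band_dist(cv2) < band_dist(cv)) {
        w <- w2; cv <- cv2; stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall > 200L) {
          w <- fresh()
          cv <- consensus_value(paste(w, collapse = ""), matrix)
          stall <- 0L
        }
      }
    }
    abort(sprintf("no window with cv in [%g, %g] found within %d tries",
                  cv_band[1], cv_band[2], max_tries))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

# Sample background sequence from the configured base composition.
sample_background <- function(n, background) {
  if (n <= 0L) return("")
  paste(sample(names(background), n, replace = TRUE, prob = background),
        collapse = "")
}

#' Generate a seeded toy genome with a ground-truth manifest
#'
#' Builds `n_genes` synthetic genes, one per contig, alternating strands.
#' Each non-decoy gene carries one AATAAA planted in its host intron at a
#' controlled distance from the 5' splice site and `n_cryptic_sites`
#' branch/acceptor pairs planted upstream of it inside controlled
#' consensus-value bands. With `scrub_spurious`, the background is cleaned
#' by point edits (and per-gene regeneration when an edit would damage a
#' planted footprint) until an internal rescan finds no unplanted hexamer
#' anywhere in the gene and no unplanted qualifying acceptor in the scanned
#' region. Deterministic: a fixed seed reproduces the output byte for byte.
#'
#' @param config A [synthetic_config()].
#' @param seed Integer seed.
#' @param params [screen_params()] used for truth flags and scrubbing.
#' @param matrices [default_matrices()].
#' @return List with `genome` (named character), `genes` (exon tibble) and
#'   `truth` (manifest tibble: one row per planted element with
#'   transcript-space and genomic coordinates, consensus values, intended
#'   pass/fail flags and intended cryptic-site ranks).
#' @export
generate_toy_genome <- function(config, seed = 1L, params = screen_params(),
                                matrices = default_matrices()) {
  stopifnot(inherits(config, "synthetic_config"))
  withr::with_seed(seed, {
    out <- purrr::map(seq_len(config$n_genes), function(g) {
      strand <- if (g %% 2L == 1L) "+" else "-"
      gene_id <- sprintf("gene%02d", g)
      for (attempt in 1:25) {
        built <- try(build_synthetic_gene(gene_id, strand, config, params,
                                          matrices), silent = TRUE)
        if (!inherits(built, "try-error")) return(built)
        if (grepl("infeasible", conditionMessage(attr(built, "condition")))) {
          stop(attr(built, "condition"))
        }
      }
      abort(paste0("could not generate a clean gene after 25 attempts: ",
                   gene_id))
    })
    genome <- stats::setNames(purrr::map_chr(out, "contig_seq"),
                              purrr::map_chr(out, "contig"))
    genes <- bind_rows(purrr::map(out, "exons"))
    truth <- bind_rows(purrr::map(out, "truth"))
    list(genome = genome, genes = genes, truth = truth)
  })
}

# Build one synthetic gene; aborts with "infeasible config" for impossible
# geometry and with ordinary errors when a sampled gene cannot be scrubbed
# (caller retries those).
build_synthetic_gene <- function(gene_id, strand, config, params, matrices) {
  n_ex <- config$n_exons
  n_in <- n_ex - 1L
  host <- if (config$decoy == "deep_intron") n_in else config$pa_intron
  if (host > n_in) {
    abort(paste0("infeasible config for ", gene_id,
                 ": host intron ordinal exceeds intron count"))
  }
  exon_lens <- sample(config$exon_len[1]:config$exon_len[2], n_ex,
                      replace = TRUE)
  intron_lens <- sample(config$other_intron_len[1]:config$other_intron_len[2],
                        n_in, replace = TRUE)
  intron_lens[host] <- sample(config$host_intron_len[1]:
                                config$host_intron_len[2], 1L)
  pa_off <- if (config$decoy == "far") 1500L else
    sample(config$pa_offset[1]:config$pa_offset[2], 1L)
  cleave_off <- pa_off + 6L + params$cleavage_offset
  if (cleave_off + 2L > intron_lens[host]) {
    abort(paste0("infeasible config for ", gene_id,
                 ": host intron too short for the planted signal"))
  }
  acc_w <- matrices$acceptor$width
  intronic_len <- matrices$acceptor$exonic_from - 1L
  br_w <- matrices$branch$width
  site_d <- config$site_dists[seq_len(config$n_cryptic_sites)]
  junctions <- pa_off - site_d
  if (config$n_cryptic_sites > 0L &&
      any(junctions - config$branch_gap - br_w < 2L)) {
    abort(paste0("infeasible config for ", gene_id,
                 ": cryptic sites do not fit between the 5'ss and the signal"))
  }
  # each planted site spans [junction - branch_gap - 7, junction]; sites
  # closer than that footprint would overwrite one another
  if (config$n_cryptic_sites > 1L &&
      any(diff(site_d) < config$branch_gap + br_w + 1L)) {
    abort(paste0("infeasible config for ", gene_id,
                 ": planted cryptic sites overlap"))
  }

  # --- transcript-space assembly -------------------------------------------
  exons <- vapply(exon_lens, sample_background, character(1),
                  background = config$background)
  introns <- vapply(intron_lens, function(n) {
    paste0("GT", sample_background(n - 4L, config$background), "AG")
  }, character(1))

  hseq <- introns[host]
  substr(hseq, pa_off + 1L, pa_off + 6L) <- "AATAAA"
  truth_sites <- NULL
  # Planted windows may not contain poly(A) hexamers, nor AG dinucleotides
  # other than the acceptor's invariant one: a stray AG would open an
  # alternative acceptor register inside a planted footprint, which the
  # scrubber could not edit without destroying the element.
  sample_clean <- function(matrix, band, allowed_ag = integer(0)) {
    for (t in 1:50) {
      w <- sample_motif_with_cv(matrix, band,
                                exclude_motifs = params$signal_set)
      if (length(setdiff(find_motif(w, "AG"), allowed_ag)) == 0L) return(w)
    }
    abort("no AG-clean motif window found")
  }
  for (i in seq_along(junctions)) {
    j <- junctions[i]
    aw <- sample_clean(matrices$acceptor, config$acceptor_cv_band,
                       allowed_ag = 11L)
    bw <- sample_clean(matrices$branch, config$branch_cv_band)
    a_start <- j - intronic_len
    b_start <- j - config$branch_gap - br_w
    substr(hseq, a_start + 1L, a_start + acc_w) <- aw
    substr(hseq, b_start + 1L, b_start + br_w) <- bw
    truth_sites <- bind_rows(
      truth_sites,
      tibble(element = c("acceptor", "branch"),
             offset_in_intron = c(a_start, b_start),
             width = c(acc_w, br_w),
             seq = c(aw, bw),
             cv = c(consensus_value(aw, matrices$acceptor),
                    consensus_value(bw, matrices$branch)),
             junction_offset = c(j, j),
             dist_to_polya = c(pa_off - j, pa_off - j)))
  }
  introns[host] <- hseq
  # intended ranks: only sites whose both consensus values clear the
  # thresholds are expected to be called; rank by distance to the signal
  if (!is.null(truth_sites)) {
    by_site <- truth_sites |>
      tidyr::pivot_wider(id_cols = c("junction_offset", "dist_to_polya"),
                         names_from = "element", values_from = "cv")
    by_site$callable <- by_site$acceptor >= params$acceptor_cv_threshold &
      by_site$branch >= params$branch_cv_threshold
    by_site$expected_rank <- NA_integer_
    by_site$expected_rank[by_site$callable] <-
      rank(by_site$dist_to_polya[by_site$callable])
    truth_sites <- truth_sites |>
      left_join(by_site |> select("junction_offset", "expected_rank"),
                by = "junction_offset")
  }

  # transcript-space gene layout
  piece_lens <- as.integer(rbind(exon_lens,
                                 c(intron_lens, 0L)))[seq_len(2L * n_ex - 1L)]
  piece_starts <- cumsum(c(0L, utils::head(piece_lens, -1L)))
  gene_seq <- paste(as.vector(rbind(exons, c(introns, "")))[
    seq_len(2L * n_ex - 1L)], collapse = "")
  intron_gene_off <- piece_starts[2L * seq_len(n_in)]
  exon_gene_off <- piece_starts[2L * seq_len(n_ex) - 1L]
  host_off <- intron_gene_off[host]

  # planted footprints in gene coordinates (donor/acceptor dinucleotides of
  # every intron are kept intact as well)
  fp <- bind_rows(
    tibble(start = host_off + pa_off, end = host_off + pa_off + 6L),
    if (!is.null(truth_sites))
      tibble(start = host_off + truth_sites$offset_in_intron,
             end = host_off + truth_sites$offset_in_intron +
               truth_sites$width),
    tibble(start = intron_gene_off, end = intron_gene_off + 2L),
    tibble(start = intron_gene_off + intron_lens - 2L,
           end = intron_gene_off + intron_lens))
  in_footprint <- function(a, b) any(a < fp$end & b > fp$start)

  # --- scrubbing -----------------------------------------------------------
  if (config$scrub_spurious) {
    for (pass in 1:100) {
      occ <- unlist(lapply(params$signal_set,
                           function(h) find_motif(gene_seq, h)))
      occ <- setdiff(sort(occ), host_off + pa_off)
      if (length(occ) == 0L) break
      o <- occ[1]
      if (in_footprint(o, o + 6L)) abort("hexamer scrub hit a footprint")
      cur <- substr(gene_seq, o + 3L, o + 3L)
      substr(gene_seq, o + 3L, o + 3L) <- if (cur == "T") "G" else "T"
      if (pass == 100L) abort("hexamer scrub did not converge")
    }
    if (config$n_cryptic_sites > 0L || config$decoy == "none") {
      planted_j <- if (is.null(truth_sites)) integer(0) else
        unique(truth_sites$junction_offset)
      expected_j <- if (is.null(truth_sites)) integer(0) else
        unique(truth_sites$junction_offset[!is.na(truth_sites$expected_rank)])
      region_start <- host_off
      # weaken a background branch window by one base: substitute the C/G
      # base with the lower frequency (neither can seed a hexamer) at the
      # position losing the most score, outside planted footprints
      weaken_branch <- function(b_start) {
        bm <- matrices$branch$freqs
        best_p <- NA_integer_; best_gain <- 0; best_b <- "C"
        for (p in seq_len(nrow(bm))) {
          gpos <- region_start + b_start + p - 1L
          if (in_footprint(gpos, gpos + 1L)) next
          obs <- substr(gene_seq, gpos + 1L, gpos + 1L)
          alt <- if (bm[p, "C"] <= bm[p, "G"]) "C" else "G"
          gain <- bm[p, obs] - bm[p, alt]
          if (gain > best_gain) {
            best_p <- p; best_gain <- gain; best_b <- alt
          }
        }
        if (is.na(best_p)) abort("branch scrub hit a footprint")
        gpos <- region_start + b_start + best_p - 1L
        substr(gene_seq, gpos + 1L, gpos + 1L) <<- best_b
      }
      for (pass in 1:50) {
        region <- substr(gene_seq, region_start + 1L,
                         region_start + pa_off)
        called <- scan_cryptic_acceptors(region, matrices, params)
        bad <- called |> filter(!.data$junction_offset %in% expected_j)
        if (nrow(bad) == 0L) break
        j <- bad$junction_offset[1]
        if (j %in% planted_j) {
          # planted sub-threshold site propped up by a background branch
          weaken_branch(bad$branch_start[1])
        } else {
          gpos <- region_start + j - 1L # the invariant G of the spurious AG
          if (in_footprint(gpos, gpos + 1L)) {
            gpos <- region_start + j - 2L # fall back to the A
            if (in_footprint(gpos, gpos + 1L)) {
              abort("acceptor scrub hit a footprint")
            }
          }
          substr(gene_seq, gpos + 1L, gpos + 1L) <- "C"
        }
        if (pass == 50L) abort("acceptor scrub did not converge")
      }
      # above-threshold planted sites must survive scrubbing; sub-threshold
      # plants (used for sharpness testing) must stay uncalled
      if (!is.null(truth_sites)) {
        expected_j <- truth_sites$junction_offset[
          truth_sites$element == "acceptor" & !is.na(truth_sites$expected_rank)]
        region <- substr(gene_seq, region_start + 1L, region_start + pa_off)
        called <- scan_cryptic_acceptors(region, matrices, params)
        if (!identical(sort(unique(called$junction_offset)),
                       sort(unique(expected_j)))) {
          abort("planted cryptic sites not recovered after scrubbing")
        }
      }
    }
  }

  # --- genomic placement ---------------------------------------------------
  flank <- config$flank
  full <- paste0(sample_background(flank, config$background), gene_seq,
                 sample_background(flank, config$background))
  if (config$scrub_spurious) {
    for (pass in 1:50) {
      occ <- unlist(lapply(params$signal_set, function(h)
        find_motif(full, h)))
      occ <- setdiff(sort(occ), flank + host_off + pa_off)
      if (length(occ) == 0L) break
      cur <- substr(full, occ[1] + 3L, occ[1] + 3L)
      substr(full, occ[1] + 3L, occ[1] + 3L) <- if (cur == "T") "G" else "T"
    }
  }
  L <- nchar(full)
  contig <- paste0("ctg_", gene_id)
  contig_seq <- if (strand == "+") full else reverse_complement(full)
  tx2gen_start <- function(a, b) {
    if (strand == "+") c(flank + a, flank + b) else c(L - flank - b, L - flank - a)
  }
  ex_iv <- purrr::map2(exon_gene_off, exon_gene_off + exon_lens, tx2gen_start)
  exons_tbl <- tibble(gene_id = gene_id, transcript_id = paste0(gene_id, ".t1"),
                      contig = contig, strand = strand,
                      start = as.integer(purrr::map_int(ex_iv, ~ as.integer(.x[1]))),
                      end = as.integer(purrr::map_int(ex_iv, ~ as.integer(.x[2]))),
                      exon_rank = seq_len(n_ex))

  # decoy genes are evaluated by the same rules as passing ones: their
  # elements are real hexamers, just mispositioned
  dist_tss <- sum(exon_lens[seq_len(host)]) + pa_off
  expect_stage1 <- dist_tss <= params$max_tss_dist &&
    host %in% params$allowed_intron_ordinals &&
    intron_lens[host] >= params$min_intron_len &&
    pa_off <= params$max_5ss_dist
  expect_refined <- expect_stage1 && pa_off < params$refined_max_5ss_dist

  pa_genomic <- if (strand == "+") flank + host_off + pa_off else
    L - 1L - (flank + host_off + pa_off)
  truth <- tibble(gene_id = gene_id, transcript_id = paste0(gene_id, ".t1"),
                  contig = contig, strand = strand,
                  element = if (config$decoy == "none") "polya" else
                    "decoy_polya",
                  intron_ordinal = host,
                  offset_in_intron = pa_off, width = 6L, seq = "AATAAA",
                  cv = NA_real_, junction_offset = NA_integer_,
                  dist_to_polya = NA_integer_, expected_rank = NA_integer_,
                  dist_from_tss = as.integer(dist_tss),
                  genomic_start = as.integer(pa_genomic),
                  expect_stage1 = expect_stage1,
                  expect_refined = expect_refined)
  if (!is.null(truth_sites)) {
    site_gstart <- if (strand == "+") {
      flank + host_off + truth_sites$offset_in_intron
    } else {
      L - (flank + host_off + truth_sites$offset_in_intron +
             truth_sites$width)
    }
    truth <- bind_rows(
      truth,
      truth_sites |>
        mutate(gene_id = gene_id, transcript_id = paste0(gene_id, ".t1"),
               contig = contig, strand = .env$strand,
               intron_ordinal = host,
               dist_from_tss = NA_integer_,
               genomic_start = as.integer(site_gstart),
               expect_stage1 = NA, expect_refined = NA) |>
        select(dplyr::all_of(names(truth))))
  }
  list(contig = contig, contig_seq = contig_seq, exons = exons_tbl,
       truth = truth)
}

#' Build a labeled transcript pool for a synthetic gene
#'
#' Runs the screen on one gene of a (synthetic) reference and materialises
#' the requested isoform kinds via [build_transcript()], anchored on the
#' most promoter-proximal refinement-passing signal and (for CSPP) its
#' rank-1 cryptic acceptor.
#'
#' @param genes,genome Gene model and sequence (may contain several genes).
#' @param kinds Character vector of kinds to build.
#' @param gene_id Gene to use (default: the first).
#' @param params,matrices Screen configuration.
#' @return Transcript tibble, one row per requested kind, with the anchor
#'   hit/acceptor attached as attributes `"pa_hit"` and `"acceptor"`.
#' @export
generate_transcript_pool <- function(genes, genome,
                                     kinds = c("mRNA", "PCPA", "CSPP"),
                                     gene_id = NULL,
                                     params = screen_params(),
                                     matrices = default_matrices()) {
  gene_id <- gene_id %||% genes$gene_id[1]
  gg <- genes |> filter(.data$gene_id == !!gene_id)
  if (nrow(gg) == 0L) abort(paste0("unknown gene: ", gene_id))
  kinds <- match.arg(kinds, c("mRNA", "pre-mRNA", "PCPA", "CSPP",
                              "read-through"), several.ok = TRUE)
  hits <- find_intronic_polya_signals(gg, genome, params) |>
    filter_promoter_proximal(params)
  best <- hits |> filter(.data$passes_refinement) |>
    arrange(.data$dist_from_tss) |> slice(1)
  acc <- NULL
  if (nrow(best) == 1L) {
    acc <- call_cryptic_acceptors(hits, gg, genome, params, matrices) |>
      filter(.data$signal_start == best$signal_start,
             .data$ordinal == best$ordinal, .data$rank == 1L)
  }
  if (any(kinds %in% c("PCPA", "CSPP", "read-through")) && nrow(best) == 0L) {
    abort(paste0("no refinement-passing poly(A) signal in ", gene_id))
  }
  if ("CSPP" %in% kinds && (is.null(acc) || nrow(acc) == 0L)) {
    abort(paste0("CSPP requested but no cryptic acceptor passes thresholds in ",
                 gene_id))
  }
  pool <- purrr::map(kinds, function(k) {
    build_transcript(gg, genome, k,
                     pa_hit = if (nrow(best)) best else NULL,
                     acceptor = acc, params = params)
  }) |> bind_rows()
  attr(pool, "pa_hit") <- if (nrow(best)) best else NULL
  attr(pool, "acceptor") <- acc
  pool
}
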
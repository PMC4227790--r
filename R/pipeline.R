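#' Run the full PCPA screen
#'
#' Stage 1 finds intronic poly(A) hexamers and applies the positional
#' filters; the refinement keeps signals < 500 bp from the 5' splice site;
#' stage 2 scans the region between the 5' splice site and each refined
#' signal for branch/acceptor pairs above the consensus-value thresholds.
#' Candidates are reported per transcript; each candidate carries its best
#' hit (smallest distance from the TSS among passing hits — promoter
#' proximity is the screen's organising principle) and the ranked cryptic
#' acceptors of that hit. The funnel report tallies both introns and genes
#' at each stage, plus the fraction of genes with any intronic signal
#' within the TSS-distance bound alone (the loose "intronic poly(A) signal
#' near the promoter" statistic, computed with the distance criterion only).
#'
#' @param genome Named character vector from [read_genome()].
#' @param genes Exon tibble from [read_annotation()].
#' @param params [screen_params()].
#' @param matrices [default_matrices()].
#' @return A `pcpa_screen` object: list with `candidates`, `hits`,
#'   `acceptors`, `funnel`, `params`.
#' @export
run_screen <- function(genome, genes, params = screen_params(),
                       matrices = default_matrices()) {
  if (is.null(genes) || nrow(genes) == 0L) {
    hits <- polya_hit_prototype()
  } else {
    hits <- find_intronic_polya_signals(genes, genome, params) |>
      filter_promoter_proximal(params)
  }
  acceptors <- call_cryptic_acceptors(hits, genes, genome, params, matrices)

  stage1 <- hits |> filter(.data$passes_stage1)
  refined <- hits |> filter(.data$passes_refinement)
  acc_keys <- acceptors |>
    distinct(.data$transcript_id, .data$ordinal, .data$signal_start) |>
    mutate(acceptor_positive = TRUE)

  best <- stage1 |>
    group_by(.data$gene_id, .data$transcript_id) |>
    arrange(.data$dist_from_tss, .data$ordinal, .data$dist_from_5ss,
            .by_group = TRUE) |>
    slice(1) |>
    ungroup()

  candidates <- best |>
    left_join(acc_keys,
              by = c("transcript_id", "ordinal", "signal_start")) |>
    mutate(acceptor_positive = !is.na(.data$acceptor_positive),
           stage = dplyr::case_when(
             .data$passes_refinement & .data$acceptor_positive ~
               "acceptor_positive",
             .data$passes_refinement ~ "refined",
             TRUE ~ "stage1")) |>
    mutate(acceptors = purrr::pmap(
      list(.data$transcript_id, .data$ordinal, .data$signal_start),
      function(t, o, s) {
        acceptors |> filter(.data$transcript_id == t, .data$ordinal == o,
                            .data$signal_start == s)
      }))

  n_genes_total <- if (is.null(genes) || nrow(genes) == 0L) 0L
    else dplyr::n_distinct(genes$gene_id)
  intron_key <- function(d) paste(d$transcript_id, d$ordinal)
  prox_genes <- if (nrow(hits)) {
    dplyr::n_distinct(hits$gene_id[hits$dist_from_tss <= params$max_tss_dist])
  } else 0L
  funnel <- tibble(
    n_introns_stage1 = dplyr::n_distinct(intron_key(stage1)),
    n_introns_refined = dplyr::n_distinct(intron_key(refined)),
    n_genes_stage1 = dplyr::n_distinct(stage1$gene_id),
    n_genes_refined = dplyr::n_distinct(refined$gene_id),
    n_genes_acceptor_positive = dplyr::n_distinct(acceptors$gene_id),
    n_genes_total = n_genes_total,
    fraction_genes_with_proximal_intronic_pA =
      if (n_genes_total > 0L) prox_genes / n_genes_total else 0)

  structure(list(candidates = candidates, hits = hits, acceptors = acceptors,
                 funnel = funnel, params = params),
            class = "pcpa_screen")
}

#' @export
print.pcpa_screen <- function(x, ...) {
  f <- x$funnel
  cat("<pcpa_screen>\n")
  cat(sprintf("  stage 1:  %d introns / %d genes with a passing signal\n",
              f$n_introns_stage1, f$n_genes_stage1))
  cat(sprintf("  refined:  %d introns / %d genes (< %d bp from the 5'ss)\n",
              f$n_introns_refined, f$n_genes_refined,
              x$params$refined_max_5ss_dist))
  cat(sprintf("  acceptor+: %d genes with a qualifying cryptic 3'ss\n",
              f$n_genes_acceptor_positive))
  cat(sprintf("  intronic pA within %d nt of the TSS: %.1f%% of genes\n",
              x$params$max_tss_dist,
              100 * f$fraction_genes_with_proximal_intronic_pA))
  invisible(x)
}

#' @describeIn run_screen Candidate table (one row per transcript reaching
#'   stage 1, with its best hit, stage label and ranked acceptors).
#' @param x A `pcpa_screen` object.
#' @param ... Unused.
#' @method tidy pcpa_screen
#' @export
tidy.pcpa_screen <- function(x, ...) {
  x$candidates
}

#' @describeIn run_screen One-row funnel summary.
#' @method glance pcpa_screen
#' @export
glance.pcpa_screen <- function(x, ...) {
  x$funnel
}

#' @describeIn run_screen Funnel bar chart (introns/genes per stage).
#' @param object A `pcpa_screen` object.
#' @method autoplot pcpa_screen
#' @export
autoplot.pcpa_screen <- function(object, ...) {
  f <- object$funnel
  df <- tibble(stage = factor(c("stage 1", "refined", "acceptor+"),
                              levels = c("stage 1", "refined", "acceptor+")),
               genes = c(f$n_genes_stage1, f$n_genes_refined,
                         f$n_genes_acceptor_positive))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stage, y = .data$genes)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "genes",
                  title = "PCPA screen funnel") +
    ggplot2::theme_minimal()
}
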
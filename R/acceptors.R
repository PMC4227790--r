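#' Scan a region for cryptic branch/acceptor pairs
#'
#' Slides the 14-mer acceptor matrix over a transcript-oriented region (the
#' intron between its 5' splice site and a downstream poly(A) hexamer) and
#' keeps windows that carry the invariant AG and score at or above the
#' acceptor consensus-value threshold. Each kept acceptor is paired with the
#' strongest branch 7-mer whose end lies within the configured spacing window
#' upstream of the cryptic junction and whose consensus value meets the
#' branch threshold; acceptors with no qualifying branch are dropped. When
#' several branch windows qualify, the highest-CV one is reported (ties:
#' nearest the junction, then 5'-most).
#'
#' @param region_seq Transcript-oriented sequence; offset 0 is the first
#'   intronic base, the sequence ends just before the poly(A) hexamer.
#' @param matrices List with `branch` and `acceptor` matrices, see
#'   [default_matrices()].
#' @param params [screen_params()] (thresholds and branch spacing).
#' @return Tibble sorted by position: `acceptor_start`, `junction_offset`
#'   (0-based offset of the exonic-side base of the cryptic junction),
#'   `acceptor_window`, `acceptor_cv`, `branch_start`, `branch_window`,
#'   `branch_cv`.
#' @export
scan_cryptic_acceptors <- function(region_seq, matrices = default_matrices(),
                                   params = screen_params()) {
  acc <- matrices$acceptor
  br <- matrices$branch
  empty <- tibble(acceptor_start = integer(0), junction_offset = integer(0),
                  acceptor_window = character(0), acceptor_cv = numeric(0),
                  branch_start = integer(0), branch_window = character(0),
                  branch_cv = numeric(0))
  n <- nchar(region_seq)
  if (n < acc$width) return(empty)
  region_seq <- toupper(region_seq)
  intronic_len <- if (is.na(acc$exonic_from)) acc$width else acc$exonic_from - 1L

  starts <- 0:(n - acc$width)
  windows <- substring(region_seq, starts + 1L, starts + acc$width)
  keep <- rep(TRUE, length(windows))
  for (p in names(acc$required_bases)) {
    keep <- keep & substring(windows, as.integer(p), as.integer(p)) ==
      acc$required_bases[[p]]
  }
  if (!any(keep)) return(empty)
  acv <- suppressWarnings(consensus_value(windows[keep], acc))
  sel <- !is.na(acv) & acv >= params$acceptor_cv_threshold
  a_start <- starts[keep][sel]
  a_win <- windows[keep][sel]
  a_cv <- acv[sel]
  if (!length(a_start)) return(empty)

  b_starts <- 0:(n - br$width)
  b_wins <- substring(region_seq, b_starts + 1L, b_starts + br$width)
  b_cv <- suppressWarnings(consensus_value(b_wins, br))

  purrr::pmap(list(a_start, a_win, a_cv), function(as_, aw, ac) {
    junction <- as_ + intronic_len
    d <- junction - (b_starts + br$width)
    ok <- !is.na(b_cv) & b_cv >= params$branch_cv_threshold &
      d >= params$branch_spacing[1] & d <= params$branch_spacing[2]
    if (!any(ok)) return(NULL)
    o <- order(-b_cv[ok], d[ok], b_starts[ok])[1]
    tibble(acceptor_start = as.integer(as_),
           junction_offset = as.integer(junction),
           acceptor_window = aw, acceptor_cv = ac,
           branch_start = as.integer(b_starts[ok][o]),
           branch_window = b_wins[ok][o], branch_cv = b_cv[ok][o])
  }) |> bind_rows() -> out
  if (nrow(out) == 0L) return(empty)
  arrange(out, .data$acceptor_start)
}

#' Rank cryptic acceptors by proximity to the poly(A) signal
#'
#' Rank 1 is the site nearest the cleavage region (smallest `dist_to_polya`);
#' ties break toward the higher acceptor consensus value, then the 5'-most
#' position. Deterministic.
#'
#' @param sites Tibble with `dist_to_polya`, `acceptor_cv` and
#'   `junction_offset` columns (one intron/poly(A) pair).
#' @return `sites` with a 1-based `rank` column, sorted by rank.
#' @export
rank_cryptic_sites <- function(sites) {
  if (nrow(sites) == 0L) {
    sites$rank <- integer(0)
    return(sites)
  }
  o <- order(sites$dist_to_polya, -sites$acceptor_cv, sites$junction_offset)
  sites <- sites[o, , drop = FALSE]
  sites$rank <- seq_len(nrow(sites))
  sites
}

#' Call cryptic acceptors upstream of passing poly(A) signals
#'
#' Stage 2 of the screen: for every hit that passed the requested filter
#' stage, the intron prefix from the 5' splice site to the hexamer start is
#' scanned with [scan_cryptic_acceptors()] and the called sites are ranked.
#'
#' @param hits Flagged hit tibble from [filter_promoter_proximal()].
#' @param genes Exon tibble.
#' @param genome Named character vector.
#' @param params [screen_params()].
#' @param matrices [default_matrices()].
#' @param stage Which hits to scan: `"refinement"` (default) or `"stage1"`.
#' @return Tibble with hit-identifying columns (`gene_id`, `transcript_id`,
#'   `ordinal`, `signal_start`, `dist_from_5ss`), acceptor columns from
#'   [scan_cryptic_acceptors()], `dist_to_polya`, `acceptor_3ss_pos`
#'   (genomic position of the exonic-side junction base) and `rank`.
#' @export
call_cryptic_acceptors <- function(hits, genes, genome,
                                   params = screen_params(),
                                   matrices = default_matrices(),
                                   stage = c("refinement", "stage1")) {
  stage <- match.arg(stage)
  flag <- if (stage == "refinement") hits$passes_refinement else hits$passes_stage1
  use <- hits[!is.na(flag) & flag, , drop = FALSE]
  proto <- tibble(gene_id = character(0), transcript_id = character(0),
                  ordinal = integer(0), contig = character(0),
                  strand = character(0), signal_start = integer(0),
                  dist_from_5ss = integer(0), acceptor_start = integer(0),
                  junction_offset = integer(0), acceptor_window = character(0),
                  acceptor_cv = numeric(0), branch_start = integer(0),
                  branch_window = character(0), branch_cv = numeric(0),
                  dist_to_polya = integer(0), acceptor_3ss_pos = integer(0),
                  rank = integer(0))
  if (nrow(use) == 0L) return(proto)
  out <- purrr::pmap(use, function(gene_id, transcript_id, ordinal, contig,
                                   strand, intron_start, intron_end,
                                   dist_from_5ss, signal_start, ...) {
    region <- substr(tx_seq(genome, contig, intron_start, intron_end, strand),
                     1L, dist_from_5ss)
    sites <- scan_cryptic_acceptors(region, matrices, params)
    if (nrow(sites) == 0L) return(NULL)
    sites$gene_id <- gene_id
    sites$transcript_id <- transcript_id
    sites$ordinal <- ordinal
    sites$contig <- contig
    sites$strand <- strand
    sites$signal_start <- signal_start
    sites$dist_from_5ss <- dist_from_5ss
    sites$dist_to_polya <- as.integer(dist_from_5ss - sites$junction_offset)
    sites$acceptor_3ss_pos <- vapply(sites$junction_offset, function(j)
      tx_offset_to_genomic(intron_start, intron_end, strand, j), integer(1))
    rank_cryptic_sites(sites)
  }) |> bind_rows()
  if (nrow(out) == 0L) return(proto)
  out[, names(proto)]
}
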
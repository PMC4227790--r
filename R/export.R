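#' Export screen results to standard files
#'
#' Writes the screen's tables and tracks to `out_dir`:
#' `candidates.tsv` (one row per candidate, flat best-hit columns),
#' `acceptors.tsv` (one row per ranked cryptic acceptor),
#' `signals.bed` / `acceptors.bed` (BED6 of passing hexamers and called
#' cryptic junctions, 0-based half-open as BED requires),
#' `transcripts.fasta` / `transcripts.gtf` (predicted PCPA and CSPP models
#' for acceptor-positive candidates) and `funnel.json`. All writers are
#' plain-text and byte-deterministic. [read_screen_results()] round-trips
#' the two TSVs.
#'
#' @param result A `pcpa_screen` from [run_screen()].
#' @param out_dir Output directory (created if needed).
#' @param genome Named character vector; needed to materialise predicted
#'   transcripts (skipped when `NULL`).
#' @param genes Exon tibble matching `result` (skipped when `NULL`).
#' @return Character vector of written paths, invisibly.
#' @export
export_results <- function(result, out_dir, genome = NULL, genes = NULL) {
  stopifnot(inherits(result, "pcpa_screen"))
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE,
                                          showWarnings = FALSE)
  if (!ok || file.access(out_dir, 2L) != 0L) {
    abort(paste0("cannot write to directory: ", out_dir))
  }
  paths <- character(0)

  cand <- result$candidates |> select(-dplyr::any_of("acceptors"))
  p <- file.path(out_dir, "candidates.tsv")
  readr::write_tsv(cand, p)
  paths <- c(paths, p)

  p <- file.path(out_dir, "acceptors.tsv")
  readr::write_tsv(result$acceptors, p)
  paths <- c(paths, p)

  sig <- result$hits |> filter(.data$passes_stage1)
  bed6 <- function(d, start, name, score) {
    tibble(chrom = d$contig, start = start, end = start + 6L,
           name = name, score = score, strand = d$strand)
  }
  p <- file.path(out_dir, "signals.bed")
  sig_start <- ifelse(sig$strand == "+", sig$signal_start,
                      sig$signal_start - 5L)
  readr::write_tsv(bed6(sig, sig_start,
                        paste0(sig$gene_id, "_pA_i", sig$ordinal),
                        as.integer(sig$passes_refinement)),
                   p, col_names = FALSE)
  paths <- c(paths, p)

  p <- file.path(out_dir, "acceptors.bed")
  acc <- result$acceptors
  acc_start <- ifelse(acc$strand == "+", acc$acceptor_3ss_pos - 2L,
                      acc$acceptor_3ss_pos - 3L)
  readr::write_tsv(tibble(chrom = acc$contig, start = acc_start,
                          end = acc_start + 6L,
                          name = paste0(acc$gene_id, "_3ss_rank", acc$rank),
                          score = round(acc$acceptor_cv, 2),
                          strand = acc$strand),
                   p, col_names = FALSE)
  paths <- c(paths, p)

  if (!is.null(genome) && !is.null(genes)) {
    tx <- export_predicted_transcripts(result, genome, genes)
    p <- file.path(out_dir, "transcripts.fasta")
    if (nrow(tx)) {
      write_fasta(stats::setNames(tx$seq, tx$name), p)
    } else {
      writeLines(character(0), p)
    }
    paths <- c(paths, p)
    p <- file.path(out_dir, "transcripts.gtf")
    writeLines(transcripts_to_gtf(tx), p)
    paths <- c(paths, p)
  }

  p <- file.path(out_dir, "funnel.json")
  jsonlite::write_json(as.list(result$funnel), p, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  paths <- c(paths, p)
  invisible(paths)
}

# Predicted PCPA/CSPP transcript models for acceptor-positive candidates.
export_predicted_transcripts <- function(result, genome, genes) {
  cands <- result$candidates |> filter(.data$stage == "acceptor_positive")
  if (nrow(cands) == 0L) {
    return(tibble(name = character(0), seq = character(0),
                  segments = list()))
  }
  purrr::map(seq_len(nrow(cands)), function(i) {
    row <- cands[i, ]
    hit <- result$hits |>
      filter(.data$transcript_id == row$transcript_id,
             .data$ordinal == row$ordinal,
             .data$signal_start == row$signal_start)
    acc <- row$acceptors[[1]] |> filter(.data$rank == 1L)
    gg <- genes |> filter(.data$transcript_id == row$transcript_id)
    pc <- build_transcript(gg, genome, "PCPA", pa_hit = hit,
                           params = result$params)
    cs <- build_transcript(gg, genome, "CSPP", pa_hit = hit, acceptor = acc,
                           params = result$params)
    bind_rows(pc, cs) |>
      mutate(name = paste0(.data$transcript_id, "_", .data$kind))
  }) |> bind_rows()
}

# Minimal GTF writer: one transcript line plus one exon line per segment,
# 1-based closed coordinates as the format requires.
transcripts_to_gtf <- function(tx) {
  if (nrow(tx) == 0L) return(character(0))
  purrr::map(seq_len(nrow(tx)), function(i) {
    segs <- tx$segments[[i]]
    attrs <- sprintf('gene_id "%s"; transcript_id "%s";',
                     tx$gene_id[i], tx$name[i])
    sprintf("%s\tpcpascreen\texon\t%d\t%d\t.\t%s\t.\t%s",
            segs$contig, segs$start + 1L, segs$end, segs$strand, attrs)
  }) |> unlist()
}

#' Read exported screen tables back
#'
#' Reconstructs the candidate and acceptor tibbles from an
#' [export_results()] directory.
#'
#' @param out_dir Directory previously written by [export_results()].
#' @return List with `candidates` and `acceptors` tibbles and the `funnel`
#'   list.
#' @export
read_screen_results <- function(out_dir) {
  list(
    candidates = readr::read_tsv(file.path(out_dir, "candidates.tsv"),
                                 show_col_types = FALSE),
    acceptors = readr::read_tsv(file.path(out_dir, "acceptors.tsv"),
                                show_col_types = FALSE),
    funnel = jsonlite::read_json(file.path(out_dir, "funnel.json"),
                                 simplifyVector = TRUE))
}
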
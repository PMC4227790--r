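#' Enumerate introns of each transcript
#'
#' Introns are the gaps between consecutive exons, numbered 1..n-1 in
#' transcription order. `five_ss` is the genomic position of the first
#' intronic base (donor side) and `three_ss` the position just past the last
#' intronic base (acceptor side), both read in transcription direction, so on
#' the minus strand `five_ss > three_ss`. `tss_offset` is the transcript-path
#' distance from the TSS to the intron's first base, i.e. the summed length
#' of all upstream exons.
#'
#' @param genes Exon tibble from [read_annotation()].
#' @return Tibble with one row per intron: `gene_id`, `transcript_id`,
#'   `ordinal`, `contig`, `strand`, `start`, `end` (0-based half-open
#'   genomic), `length`, `five_ss`, `three_ss`, `tss_offset`.
#' @export
enumerate_introns <- function(genes) {
  genes |>
    arrange(.data$transcript_id, .data$exon_rank) |>
    group_by(.data$gene_id, .data$transcript_id, .data$contig, .data$strand) |>
    summarise(intron = list({
      n <- n()
      if (n < 2L) {
        tibble(ordinal = integer(0), start = integer(0), end = integer(0),
               tss_offset = integer(0))
      } else {
        s <- .data$start; e <- .data$end
        exlen <- e - s
        if (first(.data$strand) == "+") {
          tibble(ordinal = seq_len(n - 1L),
                 start = e[-n], end = s[-1L],
                 tss_offset = cumsum(exlen)[-n])
        } else {
          tibble(ordinal = seq_len(n - 1L),
                 start = e[-1L], end = s[-n],
                 tss_offset = cumsum(exlen)[-n])
        }
      }
    }), .groups = "drop") |>
    tidyr::unnest("intron") |>
    mutate(length = .data$end - .data$start,
           five_ss = ifelse(.data$strand == "+", .data$start, .data$end - 1L),
           three_ss = ifelse(.data$strand == "+", .data$end, .data$start - 1L)) |>
    mutate(across(c("start", "end", "length", "five_ss", "three_ss",
                    "tss_offset"), as.integer)) |>
    filter(.data$length >= 1L) |>
    arrange(.data$gene_id, .data$transcript_id, .data$ordinal)
}

#' Find intronic poly(A) signal hexamers
#'
#' Scans every intron (in transcription orientation) for the configured
#' signal hexamers and records the three distances the screen filters on.
#' Occurrences straddling an exon/intron boundary are not intronic and never
#' reported; exonic occurrences are ignored. Filtering is separate — see
#' [filter_promoter_proximal()] — so the pass flags come back `NA`.
#'
#' @param genes Exon tibble.
#' @param genome Named character vector from [read_genome()].
#' @param params [screen_params()].
#' @return Tibble of hits: intron columns plus `hexamer`, `signal_start`
#'   (genomic position of the transcription-first base of the hexamer),
#'   `dist_from_5ss`, `dist_from_tss`, `passes_stage1`, `passes_refinement`.
#' @export
find_intronic_polya_signals <- function(genes, genome, params = screen_params()) {
  introns <- enumerate_introns(genes)
  if (nrow(introns) == 0L) return(polya_hit_prototype())
  oob <- introns$start < 0L | introns$end > nchar(genome)[introns$contig]
  if (any(oob)) {
    abort(paste0("intron outside contig bounds in transcript(s): ",
                 paste(unique(introns$transcript_id[oob]), collapse = ", ")))
  }
  hits <- purrr::pmap(introns, function(contig, strand, start, end, ...) {
    row <- list(...)
    s <- tx_seq(genome, contig, start, end, strand)
    purrr::map(params$signal_set, function(hex) {
      off <- find_motif(s, hex, allow_overlap = TRUE)
      if (length(off) == 0L) return(NULL)
      tibble(gene_id = row$gene_id, transcript_id = row$transcript_id,
             ordinal = row$ordinal, contig = contig, strand = strand,
             intron_start = start, intron_end = end,
             intron_length = end - start,
             five_ss = row$five_ss, three_ss = row$three_ss,
             hexamer = hex,
             signal_start = vapply(off, function(o)
               tx_offset_to_genomic(start, end, strand, o), integer(1)),
             dist_from_5ss = off,
             dist_from_tss = row$tss_offset + off)
    }) |> bind_rows()
  }) |> bind_rows()
  if (nrow(hits) == 0L) return(polya_hit_prototype())
  hits |>
    mutate(across(c("dist_from_5ss", "dist_from_tss", "signal_start"),
                  as.integer),
           passes_stage1 = NA, passes_refinement = NA) |>
    arrange(.data$gene_id, .data$transcript_id, .data$ordinal,
            .data$dist_from_5ss)
}

polya_hit_prototype <- function() {
  tibble(gene_id = character(0), transcript_id = character(0),
         ordinal = integer(0), contig = character(0), strand = character(0),
         intron_start = integer(0), intron_end = integer(0),
         intron_length = integer(0), five_ss = integer(0),
         three_ss = integer(0), hexamer = character(0),
         signal_start = integer(0), dist_from_5ss = integer(0),
         dist_from_tss = integer(0), passes_stage1 = logical(0),
         passes_refinement = logical(0))
}

#' Apply the promoter-proximal positional filters
#'
#' Stage 1 passes a hit lying within `max_tss_dist` of the TSS (inclusive),
#' in an allowed intron ordinal of at least `min_intron_len`, and within
#' `max_5ss_dist` of the 5' splice site (inclusive). The refinement
#' additionally requires the hexamer to start strictly less than
#' `refined_max_5ss_dist` from the 5' splice site. Input order is preserved.
#'
#' @param hits Tibble from [find_intronic_polya_signals()].
#' @param params [screen_params()].
#' @return `hits` with `passes_stage1` and `passes_refinement` set.
#' @export
filter_promoter_proximal <- function(hits, params = screen_params()) {
  hits |>
    mutate(passes_stage1 =
             .data$dist_from_tss <= params$max_tss_dist &
             .data$ordinal %in% params$allowed_intron_ordinals &
             .data$intron_length >= params$min_intron_len &
             .data$dist_from_5ss <= params$max_5ss_dist,
           passes_refinement = .data$passes_stage1 &
             .data$dist_from_5ss < params$refined_max_5ss_dist)
}
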
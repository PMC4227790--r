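#' Build an isoform model for a gene
#'
#' Materialises one of the transcript kinds the screen reasons about:
#' \describe{
#'   \item{mRNA}{the annotated spliced product (all exons), polyadenylated.}
#'   \item{pre-mRNA}{the unspliced primary transcript, not polyadenylated.}
#'   \item{PCPA}{premature cleavage and polyadenylation at an intronic
#'     signal: upstream exon(s) plus the host-intron prefix up to the modeled
#'     cleavage position (hexamer end + `cleavage_offset`), polyadenylated.
#'     The composite terminal exon is the last annotated exon fused to the
#'     retained intron prefix.}
#'   \item{CSPP}{the cryptically spliced product of PCPA: identical to PCPA
#'     except the interval from the authentic 5' splice site to the cryptic
#'     3' junction is excised, so only the intron segment from the cryptic
#'     junction to the cleavage position is retained.}
#'   \item{read-through}{transcription past the signal without cleavage:
#'     upstream exon(s) plus intron sequence extending
#'     `readthrough_extension` nt beyond the modeled cleavage position, not
#'     polyadenylated.}
#' }
#' Polyadenylated kinds carry a modeled tail of `params$polya_tail_len` As.
#'
#' @param genes Exon tibble (one transcript).
#' @param genome Named character vector.
#' @param kind One of `"mRNA"`, `"pre-mRNA"`, `"PCPA"`, `"CSPP"`,
#'   `"read-through"`.
#' @param pa_hit One-row hit tibble (required for PCPA/CSPP/read-through).
#' @param acceptor One-row ranked acceptor tibble (required for CSPP).
#' @param params [screen_params()] (cleavage offset, tail length).
#' @param transcript_id Transcript to build when `genes` holds several.
#' @param readthrough_extension nt of intron retained past the cleavage
#'   position for read-through models.
#' @return One-row tibble: `kind`, `gene_id`, `transcript_id`,
#'   `polyadenylated`, `cleavage_pos` (genomic, `NA` when uncleaved),
#'   `tail_len`, `seq`, and a `segments` list-column of genomic intervals
#'   (contig/start/end/strand/label) joined 5'-to-3'.
#' @export
build_transcript <- function(genes, genome, kind, pa_hit = NULL,
                             acceptor = NULL, params = screen_params(),
                             transcript_id = NULL,
                             readthrough_extension = 200L) {
  kind <- match.arg(kind, c("mRNA", "pre-mRNA", "PCPA", "CSPP", "read-through"))
  if (is.null(transcript_id)) {
    transcript_id <- if (!is.null(pa_hit)) pa_hit$transcript_id[1]
    else genes$transcript_id[1]
  }
  ex <- genes |> filter(.data$transcript_id == !!transcript_id) |>
    arrange(.data$exon_rank)
  if (nrow(ex) == 0L) abort(paste0("unknown transcript: ", transcript_id))
  strand <- ex$strand[1]
  contig <- ex$contig[1]
  tail_len <- params$polya_tail_len

  seg_tbl <- function(start, end, label) {
    tibble(contig = contig, start = as.integer(start), end = as.integer(end),
           strand = strand, label = label)
  }
  exon_segs <- function(k) {
    purrr::map2(ex$start[seq_len(k)], ex$end[seq_len(k)],
                ~ seg_tbl(.x, .y, "exon")) |> bind_rows() |>
      mutate(label = paste0("exon", row_number()))
  }
  # intron segment between transcript-space offsets [a, b) of the host intron
  intron_seg <- function(hit, a, b, label) {
    if (strand == "+") {
      seg_tbl(hit$intron_start + a, hit$intron_start + b, label)
    } else {
      seg_tbl(hit$intron_end - b, hit$intron_end - a, label)
    }
  }

  need_hit <- kind %in% c("PCPA", "CSPP", "read-through")
  if (need_hit && is.null(pa_hit)) {
    abort(paste0(kind, " requires a poly(A) signal hit"))
  }
  cleavage_pos <- NA_integer_
  if (need_hit) {
    hit <- pa_hit[1, ]
    cleave_off <- hit$dist_from_5ss + 6L + params$cleavage_offset
    if (cleave_off > hit$intron_length) {
      abort("cleavage position falls outside the host intron")
    }
  }

  if (kind == "mRNA") {
    segs <- exon_segs(nrow(ex))
    polyA <- TRUE
  } else if (kind == "pre-mRNA") {
    span <- range(c(ex$start, ex$end))
    segs <- seg_tbl(span[1], span[2], "pre-mRNA")
    polyA <- FALSE
    tail_len <- 0L
  } else if (kind == "PCPA") {
    segs <- bind_rows(exon_segs(hit$ordinal),
                      intron_seg(hit, 0L, cleave_off, "intron-prefix"))
    cleavage_pos <- tx_offset_to_genomic(hit$intron_start, hit$intron_end,
                                         strand, cleave_off - 1L)
    polyA <- TRUE
  } else if (kind == "CSPP") {
    if (is.null(acceptor) || nrow(acceptor) == 0L) {
      abort("CSPP requires a cryptic acceptor passing both thresholds")
    }
    acc <- acceptor[1, ]
    if (acc$junction_offset >= cleave_off) {
      abort("cryptic acceptor lies downstream of the cleavage position")
    }
    donor <- substr(tx_seq(genome, contig, hit$intron_start, hit$intron_end,
                           strand), 1L, 2L)
    if (toupper(donor) != "GT") {
      abort("cryptic splicing needs a functional GT donor at the 5' splice site")
    }
    segs <- bind_rows(exon_segs(hit$ordinal),
                      intron_seg(hit, acc$junction_offset, cleave_off,
                                 "cryptic-terminal"))
    cleavage_pos <- tx_offset_to_genomic(hit$intron_start, hit$intron_end,
                                         strand, cleave_off - 1L)
    polyA <- TRUE
  } else { # read-through
    rt_off <- min(cleave_off + as.integer(readthrough_extension),
                  hit$intron_length)
    segs <- bind_rows(exon_segs(hit$ordinal),
                      intron_seg(hit, 0L, rt_off, "read-through"))
    polyA <- FALSE
    tail_len <- 0L
  }

  body <- paste(purrr::pmap_chr(segs, function(contig, start, end, strand, ...)
    tx_seq(genome, contig, start, end, strand)), collapse = "")
  seq <- if (polyA) paste0(body, strrep("A", tail_len)) else body
  tibble(kind = kind, gene_id = ex$gene_id[1], transcript_id = transcript_id,
         polyadenylated = polyA, cleavage_pos = as.integer(cleavage_pos),
         tail_len = if (polyA) as.integer(tail_len) else 0L,
         seq = seq, segments = list(segs))
}

#' Extract the cis-element around an intronic poly(A) signal
#'
#' Cuts the intron fragment spanning `upstream_pad` nt upstream to
#' `downstream_pad` nt downstream of the hexamer (transcript orientation),
#' the construction used to port a PCPA-competent element into reporter
#' constructs. Defaults reproduce the -157..+51 fragment geometry.
#'
#' @param genes Exon tibble.
#' @param genome Named character vector.
#' @param pa_hit One-row hit tibble.
#' @param upstream_pad,downstream_pad Pad lengths in nt.
#' @return A `cis_element`: list with `seq` (length
#'   `upstream_pad + 6 + downstream_pad`, hexamer at 0-based offset
#'   `upstream_pad`), `hexamer`, `upstream_pad`, `downstream_pad`,
#'   `source_gene`.
#' @export
extract_cis_element <- function(genes, genome, pa_hit, upstream_pad = 157L,
                                downstream_pad = 51L) {
  hit <- pa_hit[1, ]
  a <- hit$dist_from_5ss - upstream_pad
  b <- hit$dist_from_5ss + 6L + downstream_pad
  if (a < 0L || b > hit$intron_length) {
    abort("cis-element pads exceed the intron boundary")
  }
  intron <- tx_seq(genome, hit$contig, hit$intron_start, hit$intron_end,
                   hit$strand)
  structure(list(seq = substr(intron, a + 1L, b),
                 hexamer = hit$hexamer,
                 upstream_pad = as.integer(upstream_pad),
                 downstream_pad = as.integer(downstream_pad),
                 source_gene = hit$gene_id),
            class = "cis_element")
}

#' @export
print.cis_element <- function(x, ...) {
  cat("<cis_element> from ", x$source_gene, ": ", nchar(x$seq), " nt (",
      x$upstream_pad, " + ", nchar(x$hexamer), " + ", x$downstream_pad,
      ")\n", sep = "")
  invisible(x)
}
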
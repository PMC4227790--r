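#' The oligo-dT adaptor primer
#'
#' Stand-in for the XbaKpnBam-style adaptor tag carried by the oligo-dT
#' reverse-transcription primer: the default sequence concatenates XbaI,
#' KpnI and BamHI sites. Reverse transcription is modeled by appending the
#' tag's reverse complement after the poly(A) tail, so this primer anneals
#' exactly once at the 3' end of every polyadenylated template.
#'
#' @param seq Adaptor sequence, configurable.
#' @return A primer tibble.
#' @export
adaptor_primer <- function(seq = "TCTAGAGGTACCGGATCC") {
  primer("adaptor", seq)
}

#' Gene-specific forward primer
#'
#' Takes the first `len` nt of exon 1 (transcript orientation), a region
#' shared by every isoform of the gene.
#'
#' @param genes Exon tibble.
#' @param genome Named character vector.
#' @param gene_id Gene to design for.
#' @param len Primer length.
#' @return A primer tibble.
#' @export
gene_forward_primer <- function(genes, genome, gene_id, len = 20L) {
  e1 <- genes |> filter(.data$gene_id == !!gene_id, .data$exon_rank == 1L)
  if (nrow(e1) == 0L) abort(paste0("unknown gene: ", gene_id))
  s <- tx_seq(genome, e1$contig[1], e1$start[1], e1$end[1], e1$strand[1])
  primer(paste0(gene_id, "_F"), substr(s, 1L, len))
}

#' Design a chimeric nested RACE primer for a transcript terminus
#'
#' The primer is a run of `t_run` Ts (annealing to the poly(A) tail)
#' followed by `anchor_len` residues complementary to the sequence
#' immediately upstream of the cleavage site, so it anneals exactly across
#' the tail/body junction of its own transcript and of any transcript
#' sharing that terminus.
#'
#' @param transcript One-row transcript tibble from [build_transcript()].
#' @param anchor_len Number of anchoring residues (>= 4).
#' @param t_run Number of leading Ts (default 12).
#' @return One-row tibble: `name`, `t_run`, `anchor`, `seq`.
#' @export
design_chimeric_primer <- function(transcript, anchor_len = 8L, t_run = 12L) {
  tr <- transcript[1, ]
  if (!isTRUE(tr$polyadenylated)) {
    abort("chimeric RACE primers target polyadenylated transcripts only")
  }
  if (anchor_len < 4L) abort("anchor_len must be at least 4")
  if (t_run < 1L) abort("t_run must be at least 1")
  body <- substr(tr$seq, 1L, nchar(tr$seq) - tr$tail_len)
  terminus <- substr(body, nchar(body) - anchor_len + 1L, nchar(body))
  tibble(name = paste0(tr$transcript_id, "_", tr$kind, "_nested"),
         t_run = as.integer(t_run),
         anchor = reverse_complement(terminus),
         seq = paste0(strrep("T", t_run), reverse_complement(terminus)))
}

#' Simulate 3' RACE with nested PCR on a transcript pool
#'
#' Reverse transcription tags every polyadenylated transcript with the
#' adaptor (non-polyadenylated templates — read-through, tail-less pre-mRNA —
#' yield no cDNA and can never amplify). The first round pairs the
#' gene-specific forward primer with the adaptor primer; the nested round
#' pairs it with a chimeric tail-anchored primer, which only amplifies
#' templates whose tail-adjacent terminus matches the primer's anchor
#' exactly. Matching is exact by default (`mismatch_tolerance` reserved for
#' relaxed anchors). Amplicon lengths are measured between the primers'
#' 5' ends. Cycle-number metadata is carried, not kinetically simulated.
#'
#' @param pool Transcript tibble (rows from [build_transcript()]).
#' @param fwd Gene-specific forward primer.
#' @param adaptor Adaptor primer, see [adaptor_primer()].
#' @param nested_rev Chimeric primer from [design_chimeric_primer()], or
#'   `NULL` to skip the nested round.
#' @param mismatch_tolerance Allowed anchor mismatches (0 = exact).
#' @return Amplicon tibble: `template_id` (pool row), `template_kind`,
#'   `round` (`"first"`/`"nested"`), `fwd_primer`, `rev_primer`, `start`,
#'   `end` (0-based half-open on the tagged template), `length`, `seq`,
#'   `cycles`.
#' @export
simulate_3race <- function(pool, fwd, adaptor = adaptor_primer(),
                           nested_rev = NULL, mismatch_tolerance = 0L) {
  proto <- tibble(template_id = integer(0), template_kind = character(0),
                  round = character(0), fwd_primer = character(0),
                  rev_primer = character(0), start = integer(0),
                  end = integer(0), length = integer(0), seq = character(0),
                  cycles = integer(0))
  if (nrow(pool) == 0L) return(proto)
  if (mismatch_tolerance != 0L) {
    abort("only exact primer matching (mismatch_tolerance = 0) is implemented")
  }
  out <- purrr::map(seq_len(nrow(pool)), function(i) {
    tr <- pool[i, ]
    if (!isTRUE(tr$polyadenylated)) return(NULL)
    tagged <- paste0(tr$seq, reverse_complement(adaptor$seq))
    f_off <- find_motif(tagged, fwd$seq)
    if (length(f_off) == 0L) return(NULL)
    f0 <- f_off[1]
    first <- tibble(template_id = i, template_kind = tr$kind,
                    round = "first", fwd_primer = fwd$name,
                    rev_primer = adaptor$name,
                    start = f0, end = nchar(tagged),
                    length = nchar(tagged) - f0,
                    seq = substr(tagged, f0 + 1L, nchar(tagged)),
                    cycles = 35L)
    nested <- NULL
    if (!is.null(nested_rev)) {
      site <- reverse_complement(nested_rev$seq[1])
      n_off <- find_motif(first$seq, site)
      if (length(n_off) > 0L) {
        n_end <- f0 + n_off[length(n_off)] + nchar(site)
        cycles <- switch(tr$kind, mRNA = 10L, PCPA = 15L, CSPP = 20L, 15L)
        nested <- tibble(template_id = i, template_kind = tr$kind,
                         round = "nested", fwd_primer = fwd$name,
                         rev_primer = nested_rev$name[1],
                         start = f0, end = n_end,
                         length = n_end - f0,
                         seq = substr(tagged, f0 + 1L, n_end),
                         cycles = cycles)
      }
    }
    bind_rows(first, nested)
  }) |> bind_rows()
  if (nrow(out) == 0L) return(proto)
  out |> mutate(across(c("template_id", "start", "end", "length", "cycles"),
                       as.integer))
}

#' Classify RACE amplicons against predicted isoform structures
#'
#' Uses junction signatures: an amplicon containing the unspliced exon/intron
#' boundary of the host intron is a PCPA product; one spanning the authentic
#' 5' splice site joined to the cryptic 3' junction is a CSPP product; one
#' spanning the annotated exon-exon junction is mRNA; anything else is
#' ambiguous.
#'
#' @param amplicons Tibble from [simulate_3race()].
#' @param genes,genome Gene model and sequence.
#' @param pa_hit One-row hit tibble identifying the host intron.
#' @param acceptor One-row acceptor tibble (the cryptic junction), or `NULL`.
#' @param k Half-width of each junction signature in nt.
#' @return `amplicons` with a `classification` column.
#' @export
classify_amplicon <- function(amplicons, genes, genome, pa_hit,
                              acceptor = NULL, k = 8L) {
  hit <- pa_hit[1, ]
  ex <- genes |> filter(.data$transcript_id == hit$transcript_id) |>
    arrange(.data$exon_rank)
  up_exon <- ex[hit$ordinal, ]
  exon_end <- tx_seq(genome, up_exon$contig, up_exon$start, up_exon$end,
                     up_exon$strand)
  exon_end <- substr(exon_end, nchar(exon_end) - k + 1L, nchar(exon_end))
  intron <- tx_seq(genome, hit$contig, hit$intron_start, hit$intron_end,
                   hit$strand)
  sig_unspliced <- paste0(exon_end, substr(intron, 1L, k))
  sig_cryptic <- if (!is.null(acceptor) && nrow(acceptor) > 0L) {
    j <- acceptor$junction_offset[1]
    paste0(exon_end, substr(intron, j + 1L, j + k))
  } else NA_character_
  sig_mrna <- if (nrow(ex) > hit$ordinal) {
    dn <- ex[hit$ordinal + 1L, ]
    dn_seq <- tx_seq(genome, dn$contig, dn$start, dn$end, dn$strand)
    paste0(exon_end, substr(dn_seq, 1L, k))
  } else NA_character_

  has <- function(seq, sig) {
    !is.na(sig) && length(find_motif(seq, sig)) > 0L
  }
  amplicons |>
    mutate(classification = purrr::map_chr(.data$seq, function(s) {
      if (has(s, sig_unspliced)) "PCPA"
      else if (has(s, sig_cryptic)) "CSPP"
      else if (has(s, sig_mrna)) "mRNA"
      else "ambiguous"
    }))
}
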
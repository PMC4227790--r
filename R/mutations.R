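#' Mutate a called element of a minigene
#'
#' Applies the minimal substitution that destroys a previously called
#' element, mirroring classic minigene mutagenesis:
#' \describe{
#'   \item{`five_ss`}{the host intron's donor GT becomes GA;}
#'   \item{`polya_signal`}{the passing hexamer becomes GGATCC;}
#'   \item{`cryptic_3ss`}{the invariant AG of the rank-`site_index` cryptic
#'     acceptor becomes AT.}
#' }
#' The target is located by running the screen on the input, so mutations
#' compose: masking the rank-1 acceptor and rescanning exposes the former
#' rank-2 site, and so on down the cascade. All edits are written
#' strand-aware; every other coordinate is untouched.
#'
#' @param genome Named character vector.
#' @param genes Exon tibble (the minigene model).
#' @param mutation `"five_ss"`, `"polya_signal"` or `"cryptic_3ss"`.
#' @param site_index Cryptic-acceptor rank to destroy (for `cryptic_3ss`).
#' @param gene_id Restrict the target search to one gene (default: the most
#'   promoter-proximal refined hit across all genes).
#' @param params [screen_params()].
#' @param matrices [default_matrices()].
#' @return List with the edited `genome` and an `edits` tibble (mutation,
#'   contig, strand, genomic_start, ref, alt in transcript orientation).
#' @export
apply_mutation <- function(genome, genes,
                           mutation = c("five_ss", "polya_signal",
                                        "cryptic_3ss"),
                           site_index = 1L, gene_id = NULL,
                           params = screen_params(),
                           matrices = default_matrices()) {
  mutation <- match.arg(mutation)
  if (!is.null(gene_id)) {
    genes <- genes |> filter(.data$gene_id == !!gene_id)
  }
  hits <- find_intronic_polya_signals(genes, genome, params) |>
    filter_promoter_proximal(params)
  ref_hits <- hits |> filter(.data$passes_refinement) |>
    arrange(.data$dist_from_tss)
  if (nrow(ref_hits) == 0L) {
    abort("no refinement-passing poly(A) signal to anchor the mutation")
  }
  hit <- ref_hits[1, ]
  intron <- tx_seq(genome, hit$contig, hit$intron_start, hit$intron_end,
                   hit$strand)

  edit_at <- function(off, alt) {
    ref <- substr(intron, off + 1L, off + nchar(alt))
    if (toupper(ref) == toupper(alt)) {
      abort("mutation would not change the target sequence")
    }
    g <- edit_tx_window(genome, hit$contig, hit$intron_start, hit$intron_end,
                        hit$strand, off, alt)
    gpos <- if (hit$strand == "+") hit$intron_start + off
            else hit$intron_end - off - nchar(alt)
    list(genome = g,
         edits = tibble(mutation = mutation, contig = hit$contig,
                        strand = hit$strand,
                        genomic_start = as.integer(gpos),
                        ref = ref, alt = alt))
  }

  if (mutation == "polya_signal") {
    return(edit_at(hit$dist_from_5ss, "GGATCC"))
  }
  if (mutation == "five_ss") {
    donor <- substr(intron, 1L, 2L)
    if (toupper(donor) != "GT") {
      abort("host intron does not start with a GT donor")
    }
    return(edit_at(0L, "GA"))
  }
  # cryptic_3ss
  acc <- call_cryptic_acceptors(hits, genes, genome, params, matrices) |>
    filter(.data$transcript_id == hit$transcript_id,
           .data$ordinal == hit$ordinal,
           .data$signal_start == hit$signal_start,
           .data$rank == site_index)
  if (nrow(acc) == 0L) {
    abort(paste0("no cryptic acceptor with rank ", site_index))
  }
  # AG -> AT is the minimal acceptor-killing substitution, but in an A-rich
  # context the new T can complete a poly(A) hexamer; fall back to AG -> AC
  # (C occurs in no signal hexamer) when it would
  n_sig <- function(g) {
    s <- tx_seq(g, hit$contig, hit$intron_start, hit$intron_end, hit$strand)
    sum(vapply(params$signal_set,
               function(h) length(find_motif(s, h)), integer(1)))
  }
  out <- edit_at(acc$junction_offset[1] - 2L, "AT")
  if (n_sig(out$genome) > n_sig(genome)) {
    out <- edit_at(acc$junction_offset[1] - 2L, "AC")
  }
  out
}
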
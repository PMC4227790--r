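#' Screen parameters
#'
#' Bundles every tunable of the promoter-proximal poly(A) screen. The
#' defaults are the screen's published operating point: signals within 5 kb
#' of the TSS, in the first or second intron of at least 1 kb, within 1 kb of
#' the 5' splice site (inclusive bounds), refined to < 500 bp (strict), with
#' consensus-value thresholds of 39.41 for the 14-mer acceptor and 50.16 for
#' the 7-mer branch site.
#'
#' @param signal_set Poly(A) hexamers searched for; the canonical AATAAA only
#'   by default (variants such as ATTAAA may be added).
#' @param max_tss_dist Maximum transcript-path distance (nt) from the TSS to
#'   the hexamer start, inclusive.
#' @param allowed_intron_ordinals Intron ordinals (transcription order) the
#'   screen considers.
#' @param min_intron_len Minimum host-intron length in nt.
#' @param max_5ss_dist Maximum distance (nt) from the intron's 5' splice site
#'   to the hexamer start, inclusive.
#' @param refined_max_5ss_dist Refinement bound on the 5'ss distance, strict.
#' @param acceptor_cv_threshold,branch_cv_threshold Minimum consensus values
#'   (0-100) for a cryptic acceptor 14-mer and its branch 7-mer.
#' @param branch_spacing Allowed distance range (nt) from the branch 7-mer's
#'   end to the cryptic junction.
#' @param cleavage_offset Modeled cleavage position, nt downstream of the
#'   hexamer end.
#' @param polya_tail_len Poly(A) tail length appended to polyadenylated
#'   transcript models.
#' @return An object of class `screen_params`.
#' @export
screen_params <- function(signal_set = "AATAAA",
                          max_tss_dist = 5000L,
                          allowed_intron_ordinals = c(1L, 2L),
                          min_intron_len = 1000L,
                          max_5ss_dist = 1000L,
                          refined_max_5ss_dist = 500L,
                          acceptor_cv_threshold = 39.41,
                          branch_cv_threshold = 50.16,
                          branch_spacing = c(18L, 44L),
                          cleavage_offset = 15L,
                          polya_tail_len = 30L) {
  stopifnot(length(signal_set) >= 1L, all(nchar(signal_set) == 6L),
            !any(grepl("[^ACGTacgt]", signal_set)))
  stopifnot(max_tss_dist > 0, min_intron_len > 0, max_5ss_dist > 0,
            refined_max_5ss_dist > 0, refined_max_5ss_dist <= max_5ss_dist)
  stopifnot(all(allowed_intron_ordinals >= 1L))
  stopifnot(acceptor_cv_threshold >= 0, acceptor_cv_threshold <= 100,
            branch_cv_threshold >= 0, branch_cv_threshold <= 100)
  stopifnot(length(branch_spacing) == 2L, branch_spacing[1] <= branch_spacing[2],
            branch_spacing[1] >= 0)
  stopifnot(cleavage_offset >= 0, polya_tail_len >= 0)
  structure(
    list(signal_set = toupper(signal_set),
         max_tss_dist = as.integer(max_tss_dist),
         allowed_intron_ordinals = as.integer(allowed_intron_ordinals),
         min_intron_len = as.integer(min_intron_len),
         max_5ss_dist = as.integer(max_5ss_dist),
         refined_max_5ss_dist = as.integer(refined_max_5ss_dist),
         acceptor_cv_threshold = acceptor_cv_threshold,
         branch_cv_threshold = branch_cv_threshold,
         branch_spacing = as.integer(branch_spacing),
         cleavage_offset = as.integer(cleavage_offset),
         polya_tail_len = as.integer(polya_tail_len)),
    class = "screen_params")
}

#' @export
print.screen_params <- function(x, ...) {
  cat("<screen_params>\n")
  cat("  signals:", paste(x$signal_set, collapse = ","),
      "| TSS dist <=", x$max_tss_dist,
      "| introns {", paste(x$allowed_intron_ordinals, collapse = ","),
      "} >=", x$min_intron_len, "nt\n")
  cat("  5'ss dist <=", x$max_5ss_dist, "(refined <", x$refined_max_5ss_dist,
      ") | CV thresholds acceptor", x$acceptor_cv_threshold,
      "branch", x$branch_cv_threshold, "\n")
  invisible(x)
}
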
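#' Read a reference genome from FASTA
#'
#' Loads a multi-record FASTA (wrapped or unwrapped) into a named character
#' vector of uppercase sequences over the alphabet \{A, C, G, T, N\}.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector, one element per contig.
#' @export
read_genome <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) abort("FASTA contains no records")
  out <- toupper(as.character(seqs))
  names(out) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(out))) abort("duplicate contig names in FASTA")
  if (any(nchar(out) == 0L)) abort("empty sequence record in FASTA")
  bad <- grepl("[^ACGTN]", out)
  if (any(bad)) {
    abort(paste0("non-ACGTN characters in contig(s): ",
                 paste(names(out)[bad], collapse = ", ")))
  }
  out
}

#' Write sequences to FASTA
#'
#' Plain unwrapped writer; output bytes are fully determined by the input,
#' so fixture files are reproducible.
#'
#' @param seqs Named character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(!is.null(names(seqs)), all(nzchar(names(seqs))))
  lines <- character(2L * length(seqs))
  lines[c(TRUE, FALSE)] <- paste0(">", names(seqs))
  lines[c(FALSE, TRUE)] <- unname(seqs)
  writeLines(lines, path)
  invisible(path)
}

#' Reverse complement of a nucleotide sequence
#'
#' Case-preserving (printed mutagenesis primers are conventionally lowercase)
#' and an involution: applying it twice returns the input.
#'
#' @param seq Character vector of sequences over \{A, C, G, T, N\} (either case).
#' @return Character vector of reverse complements.
#' @export
#' @examples
#' reverse_complement("gttgctcattaacggatatcttaacg")
reverse_complement <- function(seq) {
  stopifnot(is.character(seq))
  if (any(grepl("[^ACGTNacgtn]", seq))) abort("non-nucleotide character in sequence")
  comp <- chartr("ACGTNacgtn", "TGCANtgcan", seq)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(x) paste(rev(x), collapse = ""), character(1))
}

#' Construct a PCR primer
#'
#' @param name Primer name.
#' @param seq Sequence written 5'-to-3', alphabet \{A, C, G, T\}.
#' @return A one-row tibble with columns `name` and `seq`.
#' @export
primer <- function(name, seq) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  stopifnot(is.character(seq), length(seq) == 1L, nzchar(seq))
  if (grepl("[^ACGTacgt]", seq)) abort("primer sequence must be over {A,C,G,T}")
  tibble(name = name, seq = seq)
}

#' Verify that two primers form a mutagenesis pair
#'
#' Site-directed mutagenesis primer pairs are exact reverse complements of
#' one another; this checks that property, case-insensitively.
#'
#' @param fwd,rev Primers from [primer()].
#' @return `TRUE` iff `rev` is the reverse complement of `fwd`.
#' @export
verify_primer_pair <- function(fwd, rev) {
  toupper(rev$seq) == toupper(reverse_complement(fwd$seq))
}

#' Find all occurrences of a motif in a sequence
#'
#' Literal matching, 0-based start offsets in ascending order. `N` in the
#' target never matches any motif position. A motif longer than the sequence
#' yields an empty result.
#'
#' @param seq Single sequence to search.
#' @param motif Motif (no ambiguity codes).
#' @param allow_overlap Report overlapping occurrences (default `TRUE`).
#' @return Integer vector of 0-based start offsets.
#' @export
find_motif <- function(seq, motif, allow_overlap = TRUE) {
  stopifnot(is.character(seq), length(seq) == 1L)
  stopifnot(is.character(motif), length(motif) == 1L, nzchar(motif))
  if (grepl("[^ACGTacgt]", motif)) abort("motif must be over {A,C,G,T}")
  if (nchar(motif) > nchar(seq)) return(integer(0))
  seq <- toupper(seq)
  motif <- toupper(motif)
  if (allow_overlap) {
    pat <- paste0("(?=", motif, ")")
    m <- gregexpr(pat, seq, perl = TRUE)[[1]]
  } else {
    m <- gregexpr(motif, seq, fixed = TRUE)[[1]]
  }
  if (m[1] == -1L) return(integer(0))
  as.integer(m) - 1L
}
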
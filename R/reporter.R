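#' Assemble a splicing reporter construct
#'
#' A minimal intron-containing reporter in the style of the two-exon
#' beta-globin CAT reporter: exon 1, an intron, a 3' exon, and a vector
#' poly(A) cassette (bovine-growth-hormone style) that terminates the
#' reporter transcript. Segment sequences are supplied by the caller (see
#' [example_reporter()] for a seeded synthetic one).
#'
#' @param name Construct name.
#' @param exon1,intron,three_prime_exon,vector_pa Segment sequences, 5'-3'.
#' @return A `reporter_construct`: list with `name`, `segments` (named
#'   character vector), `insertions` (tibble of performed insertions).
#' @export
reporter_construct <- function(name, exon1, intron, three_prime_exon,
                               vector_pa) {
  segs <- c(exon1 = exon1, intron = intron,
            three_prime_exon = three_prime_exon, vector_pa = vector_pa)
  stopifnot(all(nzchar(segs)), !any(grepl("[^ACGTNacgtn]", segs)))
  structure(list(name = name, segments = segs,
                 insertions = tibble(element_source = character(0),
                                     site = character(0), at = integer(0))),
            class = "reporter_construct")
}

#' @export
print.reporter_construct <- function(x, ...) {
  cat("<reporter_construct> ", x$name, "\n", sep = "")
  for (s in names(x$segments)) {
    cat("  ", format(s, width = 16), nchar(x$segments[[s]]), "nt\n")
  }
  if (nrow(x$insertions)) {
    cat("  insertions:", paste(x$insertions$element_source, "into",
                               x$insertions$site, collapse = "; "), "\n")
  }
  invisible(x)
}

#' A seeded synthetic reporter construct
#'
#' Generates segment sequences with no poly(A) hexamer outside the vector
#' cassette, which carries a single AATAAA. Deterministic under `seed`.
#'
#' @param seed Integer seed.
#' @param exon1_len,intron_len,exon2_len,vector_pa_len Segment lengths.
#' @return A `reporter_construct`.
#' @export
example_reporter <- function(seed = 1L, exon1_len = 180L, intron_len = 1100L,
                             exon2_len = 220L, vector_pa_len = 120L) {
  withr::with_seed(seed, {
    rand <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")
    clean <- function(n) {
      s <- rand(n)
      while (length(find_motif(s, "AATAAA")) > 0L) s <- rand(n)
      s
    }
    vp <- clean(vector_pa_len)
    mid <- vector_pa_len %/% 2L
    substr(vp, mid + 1L, mid + 6L) <- "AATAAA"
    reporter_construct("synthetic-CAT(In)",
                       exon1 = clean(exon1_len),
                       intron = paste0("GT", clean(intron_len - 4L), "AG"),
                       three_prime_exon = clean(exon2_len),
                       vector_pa = vp)
  })
}

#' Insert a cis-element into a reporter construct
#'
#' Places the element sequence exactly once at the configured insertion point
#' of the requested site (the segment midpoint by default). With
#' `neutralize_vector_pa`, every AATAAA in the vector poly(A) cassette is
#' replaced by GGATCC so the vector signal cannot compete with the element's
#' (the classic aataaa-to-ggatcc substitution).
#'
#' @param construct A `reporter_construct`.
#' @param element A `cis_element` from [extract_cis_element()].
#' @param site `"intron"` or `"three_prime_exon"`.
#' @param neutralize_vector_pa Destroy vector-cassette AATAAA hexamers.
#' @param at 0-based offset within the site segment at which to insert
#'   (default: segment midpoint).
#' @return The modified `reporter_construct`.
#' @export
insert_cis_element <- function(construct, element,
                               site = c("intron", "three_prime_exon"),
                               neutralize_vector_pa = FALSE, at = NULL) {
  site <- match.arg(site)
  segs <- construct$segments
  target <- segs[[site]]
  at <- at %||% (nchar(target) %/% 2L)
  stopifnot(at >= 0L, at <= nchar(target))
  segs[[site]] <- paste0(substr(target, 1L, at), element$seq,
                         substr(target, at + 1L, nchar(target)))
  if (neutralize_vector_pa) {
    segs[["vector_pa"]] <- neutralize_polya(segs[["vector_pa"]])
  }
  construct$segments <- segs
  construct$insertions <- bind_rows(
    construct$insertions,
    tibble(element_source = element$source_gene, site = site,
           at = as.integer(at)))
  construct
}

# Replace every AATAAA occurrence (case-preserved) with GGATCC; repeated
# until no occurrence remains so overlapping hexamers cannot survive.
neutralize_polya <- function(seq) {
  repeat {
    off <- find_motif(seq, "AATAAA")
    if (length(off) == 0L) return(seq)
    o <- off[1]
    repl <- if (substr(seq, o + 1L, o + 1L) %in% c("a", "c", "g", "t"))
      "ggatcc" else "GGATCC"
    substr(seq, o + 1L, o + 6L) <- repl
  }
}

#' Express a reporter construct as a gene model
#'
#' Flattens the construct into a single-contig genome and a two-exon gene
#' (exon 1; intron; 3' exon fused to the vector cassette), so the same
#' screen that runs on genomic annotation can run on the reporter.
#'
#' @param construct A `reporter_construct`.
#' @return List with `genome` and `genes`, as from [load_reference()].
#' @export
reporter_gene_model <- function(construct) {
  segs <- toupper(construct$segments)
  lens <- nchar(segs)
  contig <- paste0("construct_", gsub("[^A-Za-z0-9]+", "_", construct$name))
  genome <- stats::setNames(paste(segs, collapse = ""), contig)
  e1 <- c(0L, lens[["exon1"]])
  e2_start <- lens[["exon1"]] + lens[["intron"]]
  e2 <- c(e2_start, e2_start + lens[["three_prime_exon"]] + lens[["vector_pa"]])
  genes <- tibble(gene_id = construct$name, transcript_id = construct$name,
                  contig = contig, strand = "+",
                  start = c(e1[1], e2[1]), end = c(e1[2], e2[2]),
                  exon_rank = c(1L, 2L))
  list(genome = genome, genes = genes)
}
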
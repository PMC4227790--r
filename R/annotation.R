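#' Read gene models from GTF/GFF3 or BED12
#'
#' Parses annotation into a tidy exon table: one row per exon, 0-based
#' half-open genomic coordinates, with `exon_rank` giving transcription order
#' (5'-to-3' on the coding strand, so minus-strand transcripts count from the
#' largest genomic coordinate). Malformed records (zero-length exons,
#' strandless transcripts) are skipped with a warning.
#'
#' @param path Annotation file; format inferred from the extension
#'   (`.bed` = BED12, `.gtf`/`.gff`/`.gff3` = GTF/GFF3) unless given.
#' @param format One of `"auto"`, `"bed"`, `"gtf"`, `"gff3"`.
#' @return Tibble with columns `gene_id`, `transcript_id`, `contig`, `strand`,
#'   `start`, `end`, `exon_rank`.
#' @export
read_annotation <- function(path, format = c("auto", "bed", "gtf", "gff3")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     bed = "bed", gtf = "gtf", gff = "gff3", gff3 = "gff3",
                     abort(paste0("cannot infer annotation format from: ", path)))
  }
  if (format == "bed") {
    gr <- rtracklayer::import(path, format = "bed")
    blocks <- rtracklayer::blocks(gr)
    rows <- purrr::map2(seq_along(gr), as.list(blocks), function(i, b) {
      tibble(
        gene_id = as.character(gr$name[i]),
        transcript_id = as.character(gr$name[i]),
        contig = as.character(GenomeInfoDb::seqnames(gr)[i]),
        strand = as.character(BiocGenerics::strand(gr)[i]),
        start = BiocGenerics::start(b) - 1L,
        end = BiocGenerics::end(b)
      )
    })
    ex <- bind_rows(rows)
  } else {
    gr <- rtracklayer::import(path, format = format)
    gr <- gr[tolower(as.character(gr$type)) == "exon"]
    if (length(gr) == 0L) abort("annotation contains no exon features")
    txid <- if (!is.null(gr$transcript_id)) {
      as.character(gr$transcript_id)
    } else if (!is.null(gr$Parent)) {
      vapply(as.list(gr$Parent), function(p) as.character(p)[1], character(1))
    } else {
      abort("exon features carry neither transcript_id nor Parent")
    }
    gid <- if (!is.null(gr$gene_id)) as.character(gr$gene_id) else txid
    gid[is.na(gid)] <- txid[is.na(gid)]
    ex <- tibble(
      gene_id = gid,
      transcript_id = txid,
      contig = as.character(GenomeInfoDb::seqnames(gr)),
      strand = as.character(BiocGenerics::strand(gr)),
      start = BiocGenerics::start(gr) - 1L,
      end = BiocGenerics::end(gr)
    )
  }
  tidy_exon_table(ex)
}

# Normalise a raw exon tibble: drop malformed records with a warning, sort
# exons into transcription order, assign exon_rank.
tidy_exon_table <- function(ex) {
  skipped <- character(0)
  bad_strand <- !ex$strand %in% c("+", "-")
  if (any(bad_strand)) {
    skipped <- c(skipped, paste0("strandless exon skipped: ",
                                 ex$transcript_id[bad_strand]))
    ex <- ex[!bad_strand, , drop = FALSE]
  }
  zero <- ex$end <= ex$start
  if (any(zero)) {
    skipped <- c(skipped, paste0("zero-length exon skipped: ",
                                 ex$transcript_id[zero]))
    ex <- ex[!zero, , drop = FALSE]
  }
  if (length(skipped)) warn(paste(skipped, collapse = "\n"))
  if (nrow(ex) == 0L) abort("no usable exon records in annotation")
  ex <- ex |>
    group_by(.data$transcript_id) |>
    arrange(.data$start, .by_group = TRUE) |>
    mutate(exon_rank = if (first(.data$strand) == "+") row_number()
           else rev(row_number())) |>
    ungroup() |>
    arrange(.data$gene_id, .data$transcript_id, .data$exon_rank)
  # overlap check within transcript (exons sorted by genomic start)
  chk <- ex |>
    group_by(.data$transcript_id) |>
    summarise(ok = {
      o <- order(.data$start)
      n() == 1L || all(utils::head(.data$end[o], -1) <=
                         utils::tail(.data$start[o], -1))
    }, .groups = "drop")
  if (!all(chk$ok)) {
    abort(paste0("overlapping exons in transcript(s): ",
                 paste(chk$transcript_id[!chk$ok], collapse = ", ")))
  }
  attr(ex, "skipped") <- skipped
  ex
}

#' Load a reference genome together with its gene models
#'
#' @param fasta_source Path to the genome FASTA.
#' @param annotation_source Path to GTF/GFF3 or BED12 gene models.
#' @param format Annotation format, see [read_annotation()].
#' @return List with elements `genome` (named character vector) and `genes`
#'   (exon tibble); a character vector of skipped-record messages is attached
#'   as the `"skipped"` attribute of `genes`.
#' @export
load_reference <- function(fasta_source, annotation_source, format = "auto") {
  genome <- read_genome(fasta_source)
  genes <- read_annotation(annotation_source, format = format)
  missing <- setdiff(unique(genes$contig), names(genome))
  if (length(missing)) {
    off <- unique(genes$gene_id[genes$contig %in% missing])
    abort(paste0("gene(s) reference contig(s) absent from FASTA: ",
                 paste(off, collapse = ", ")))
  }
  oob <- genes$end > nchar(genome)[genes$contig] | genes$start < 0L
  if (any(oob)) {
    abort(paste0("exon outside contig bounds for gene(s): ",
                 paste(unique(genes$gene_id[oob]), collapse = ", ")))
  }
  list(genome = genome, genes = genes)
}

#' Transcription start sites of an exon table
#'
#' The TSS is the transcription-order first exon's first base: the smallest
#' genomic coordinate for plus-strand transcripts, the largest (end - 1) for
#' minus-strand ones.
#'
#' @param genes Exon tibble from [read_annotation()].
#' @return Tibble with `gene_id`, `transcript_id`, `contig`, `strand`, `tss`.
#' @export
transcript_tss <- function(genes) {
  genes |>
    filter(.data$exon_rank == 1L) |>
    mutate(tss = ifelse(.data$strand == "+", .data$start, .data$end - 1L)) |>
    select("gene_id", "transcript_id", "contig", "strand", "tss")
}

# Sequence of a genomic interval read in transcription orientation.
tx_seq <- function(genome, contig, start, end, strand) {
  s <- substr(genome[[contig]], start + 1L, end)
  if (strand == "-") reverse_complement(s) else s
}

# Genomic position of the base at transcript-orientation offset `off` within
# a genomic interval [start, end).
tx_offset_to_genomic <- function(start, end, strand, off) {
  if (strand == "-") end - 1L - off else start + off
}

# Apply a replacement at transcript-orientation offsets [off, off + width)
# of interval [start, end); `replacement` is written in transcript
# orientation. Returns the edited genome.
edit_tx_window <- function(genome, contig, start, end, strand, off, replacement) {
  w <- nchar(replacement)
  if (strand == "-") {
    g_start <- end - off - w   # 0-based
    replacement <- reverse_complement(replacement)
  } else {
    g_start <- start + off
  }
  seq <- genome[[contig]]
  substr(seq, g_start + 1L, g_start + w) <- replacement
  genome[[contig]] <- seq
  genome
}
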
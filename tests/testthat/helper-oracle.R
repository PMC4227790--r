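# Brute-force reference implementations, deliberately naive: explicit
# nested loops, no shared helpers with the package, sequence handling via
# Biostrings. They recompute every distance from scratch and serve as the
# independent oracle the production screen is compared against.

oracle_revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(toupper(s))))
}

# All intronic poly(A)-signal occurrences with distances and filter flags.
oracle_polya_hits <- function(genes, genome, params) {
  rows <- list()
  for (tx in unique(genes$transcript_id)) {
    ex <- genes[genes$transcript_id == tx, ]
    ex <- ex[order(ex$exon_rank), ]
    strand <- ex$strand[1]
    contig <- ex$contig[1]
    if (nrow(ex) < 2L) next
    up_len <- 0L
    for (k in 1:(nrow(ex) - 1L)) {
      up_len <- up_len + (ex$end[k] - ex$start[k])
      if (strand == "+") {
        g_lo <- ex$end[k]; g_hi <- ex$start[k + 1L]
      } else {
        g_lo <- ex$end[k + 1L]; g_hi <- ex$start[k]
      }
      ilen <- g_hi - g_lo
      if (ilen < 1L) next
      iseq <- substr(genome[[contig]], g_lo + 1L, g_hi)
      if (strand == "-") iseq <- oracle_revcomp(iseq)
      for (hex in params$signal_set) {
        if (ilen < nchar(hex)) next
        for (i in 0:(ilen - nchar(hex))) {
          if (substr(iseq, i + 1L, i + nchar(hex)) == hex) {
            s1 <- (up_len + i) <= params$max_tss_dist &&
              k %in% params$allowed_intron_ordinals &&
              ilen >= params$min_intron_len &&
              i <= params$max_5ss_dist
            rows[[length(rows) + 1L]] <- data.frame(
              gene_id = ex$gene_id[1], transcript_id = tx, ordinal = k,
              hexamer = hex,
              signal_start = if (strand == "+") g_lo + i else g_hi - 1L - i,
              dist_from_5ss = i, dist_from_tss = up_len + i,
              passes_stage1 = s1,
              passes_refinement = s1 && i < params$refined_max_5ss_dist,
              stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(gene_id = character(0), transcript_id = character(0),
                      ordinal = integer(0), hexamer = character(0),
                      signal_start = integer(0), dist_from_5ss = integer(0),
                      dist_from_tss = integer(0), passes_stage1 = logical(0),
                      passes_refinement = logical(0))
  }
  out[order(out$transcript_id, out$ordinal, out$dist_from_5ss,
            out$hexamer), , drop = FALSE]
}

# Straight-line consensus value.
oracle_cv <- function(window, m) {
  b <- strsplit(toupper(window), "")[[1]]
  s <- 0; smin <- 0; smax <- 0
  for (p in seq_len(m$width)) {
    s <- s + m$freqs[p, b[p]]
    smin <- smin + min(m$freqs[p, ])
    smax <- smax + max(m$freqs[p, ])
  }
  100 * (s - smin) / (smax - smin)
}

# Every qualifying (branch, acceptor) pair in a region, nested loops,
# including the best-branch choice and the final ranking.
oracle_scan <- function(region, matrices, params) {
  region <- toupper(region)
  acc <- matrices$acceptor; br <- matrices$branch
  n <- nchar(region)
  ilen <- acc$exonic_from - 1L
  out <- list()
  if (n < acc$width) return(out)
  for (a in 0:(n - acc$width)) {
    w <- substr(region, a + 1L, a + acc$width)
    ok <- TRUE
    for (p in names(acc$required_bases)) {
      if (substr(w, as.integer(p), as.integer(p)) != acc$required_bases[[p]])
        ok <- FALSE
    }
    if (!ok || grepl("N", w)) next
    acv <- oracle_cv(w, acc)
    if (acv < params$acceptor_cv_threshold) next
    junction <- a + ilen
    best <- NULL
    for (b in 0:(n - br$width)) {
      d <- junction - (b + br$width)
      if (d < params$branch_spacing[1] || d > params$branch_spacing[2]) next
      bw <- substr(region, b + 1L, b + br$width)
      if (grepl("N", bw)) next
      bcv <- oracle_cv(bw, br)
      if (bcv < params$branch_cv_threshold) next
      cand <- list(start = b, window = bw, cv = bcv, d = d)
      if (is.null(best) || cand$cv > best$cv + 1e-12 ||
          (abs(cand$cv - best$cv) <= 1e-12 && cand$d < best$d)) {
        best <- cand
      }
    }
    if (is.null(best)) next
    out[[length(out) + 1L]] <- data.frame(
      acceptor_start = a, junction_offset = junction, acceptor_window = w,
      acceptor_cv = acv, branch_start = best$start,
      branch_window = best$window, branch_cv = best$cv,
      stringsAsFactors = FALSE)
  }
  out
}

# Cryptic-acceptor calls for every refinement-passing oracle hit.
oracle_acceptors <- function(genes, genome, params, matrices) {
  hits <- oracle_polya_hits(genes, genome, params)
  hits <- hits[hits$passes_refinement, , drop = FALSE]
  rows <- list()
  if (nrow(hits)) for (h in seq_len(nrow(hits))) {
    tx <- hits$transcript_id[h]; k <- hits$ordinal[h]
    ex <- genes[genes$transcript_id == tx, ]
    ex <- ex[order(ex$exon_rank), ]
    strand <- ex$strand[1]
    if (strand == "+") {
      g_lo <- ex$end[k]; g_hi <- ex$start[k + 1L]
    } else {
      g_lo <- ex$end[k + 1L]; g_hi <- ex$start[k]
    }
    iseq <- substr(genome[[ex$contig[1]]], g_lo + 1L, g_hi)
    if (strand == "-") iseq <- oracle_revcomp(iseq)
    region <- substr(iseq, 1L, hits$dist_from_5ss[h])
    found <- oracle_scan(region, matrices, params)
    if (!length(found)) next
    df <- do.call(rbind, found)
    df$gene_id <- hits$gene_id[h]; df$transcript_id <- tx; df$ordinal <- k
    df$signal_start <- hits$signal_start[h]
    df$dist_to_polya <- hits$dist_from_5ss[h] - df$junction_offset
    df <- df[order(df$dist_to_polya, -df$acceptor_cv,
                   df$junction_offset), , drop = FALSE]
    df$rank <- seq_len(nrow(df))
    rows[[length(rows) + 1L]] <- df
  }
  if (!length(rows)) {
    return(data.frame(gene_id = character(0), transcript_id = character(0),
                      ordinal = integer(0), signal_start = integer(0),
                      junction_offset = integer(0), acceptor_cv = numeric(0),
                      branch_start = integer(0), branch_cv = numeric(0),
                      dist_to_polya = integer(0), rank = integer(0)))
  }
  do.call(rbind, rows)
}

# Exhaustive motif offsets by window comparison.
oracle_find_motif <- function(seq, motif) {
  seq <- toupper(seq); motif <- toupper(motif)
  hits <- integer(0)
  if (nchar(motif) > nchar(seq)) return(hits)
  for (i in 0:(nchar(seq) - nchar(motif))) {
    if (substr(seq, i + 1L, i + nchar(motif)) == motif) {
      hits <- c(hits, i)
    }
  }
  hits
}
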
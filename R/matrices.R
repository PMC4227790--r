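#' Read a splice-signal frequency matrix
#'
#' Plain-text format: comment lines (`#`) carrying metadata (`name:`,
#' `bases:`, `required:` as `pos=BASE` pairs, `exonic_from:` the first
#' exonic position), then one row per position of four tab-separated base
#' frequencies in the stated base order. Frequencies must sum to 1 per
#' position (tolerance 1e-6).
#'
#' @param path Path to the matrix file.
#' @return A `freq_matrix` object: list with `name`, `width`, `freqs`
#'   (width x 4 matrix, columns A/C/G/T), `required_bases` (named character,
#'   names are 1-based positions), `exonic_from` (first exonic position, or
#'   `NA` for a fully intronic motif).
#' @export
read_freq_matrix <- function(path) {
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  get_meta <- function(key) {
    m <- grep(paste0("^#\\s*", key, ":"), meta, value = TRUE)
    if (!length(m)) return(NA_character_)
    trimws(sub(paste0("^#\\s*", key, ":"), "", m[1]))
  }
  name <- get_meta("name")
  bases <- strsplit(get_meta("bases"), "\\s+")[[1]]
  if (length(bases) != 4L || !setequal(bases, c("A", "C", "G", "T"))) {
    abort("matrix header must name the four bases")
  }
  freqs <- do.call(rbind, lapply(strsplit(body, "\t"), as.numeric))
  colnames(freqs) <- bases
  freqs <- freqs[, c("A", "C", "G", "T"), drop = FALSE]
  req <- character(0)
  rq <- get_meta("required")
  if (!is.na(rq)) {
    kv <- strsplit(strsplit(rq, "\\s+")[[1]], "=")
    req <- vapply(kv, `[`, character(1), 2)
    names(req) <- vapply(kv, `[`, character(1), 1)
  }
  ef <- suppressWarnings(as.integer(get_meta("exonic_from")))
  freq_matrix(name = name, freqs = freqs, required_bases = req,
              exonic_from = ef)
}

#' Construct a frequency matrix object
#'
#' @param name Matrix name.
#' @param freqs Numeric matrix, one row per position, columns A/C/G/T.
#' @param required_bases Named character vector of invariant bases (names =
#'   1-based positions), e.g. the acceptor AG.
#' @param exonic_from First exonic position (1-based) for acceptor-style
#'   motifs whose window crosses the junction; `NA` otherwise.
#' @return A `freq_matrix` object.
#' @export
freq_matrix <- function(name, freqs, required_bases = character(0),
                        exonic_from = NA_integer_) {
  stopifnot(is.matrix(freqs), ncol(freqs) == 4L,
            identical(colnames(freqs), c("A", "C", "G", "T")))
  if (any(freqs < 0)) abort("negative frequency in matrix")
  if (any(abs(rowSums(freqs) - 1) > 1e-6)) {
    abort("per-position frequencies must sum to 1")
  }
  if (length(required_bases)) {
    pos <- as.integer(names(required_bases))
    stopifnot(!anyNA(pos), all(pos >= 1L), all(pos <= nrow(freqs)),
              all(required_bases %in% c("A", "C", "G", "T")))
  }
  structure(list(name = name, width = nrow(freqs), freqs = freqs,
                 required_bases = required_bases,
                 exonic_from = as.integer(exonic_from)),
            class = "freq_matrix")
}

#' @export
print.freq_matrix <- function(x, ...) {
  cat("<freq_matrix> ", x$name, ": ", x$width, " positions", sep = "")
  if (length(x$required_bases)) {
    cat(" | required ", paste0(names(x$required_bases), "=",
                               x$required_bases, collapse = " "), sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Load the shipped branch and acceptor matrices
#'
#' Returns the package's default 7-mer branch-site and 14-mer 3'-splice-site
#' frequency matrices. The acceptor window covers 13 intronic positions
#' ending in the invariant AG plus one exonic position; the junction falls
#' after position 13. These defaults are synthetic tables built from the
#' consensus descriptions of the human signals (pyrimidine-rich acceptor
#' tract, near-invariant branch-point adenosine); substitute your own files
#' via [read_freq_matrix()] for production genome scans.
#'
#' @return Named list with elements `branch` and `acceptor`.
#' @export
default_matrices <- function() {
  dir <- system.file("extdata", "matrices", package = "pcpascreen")
  list(branch = read_freq_matrix(file.path(dir, "branch_7mer.tsv")),
       acceptor = read_freq_matrix(file.path(dir, "acceptor_14mer.tsv")))
}

#' Consensus value of a sequence window
#'
#' The Shapiro-Senapathy normalised score
#' `cv = 100 (S - Smin) / (Smax - Smin)`, where `S` sums the matrix frequency
#' of the observed base at each position and `Smin`/`Smax` sum the
#' per-position minimum/maximum frequencies. A window matching the
#' per-position argmax base at every position scores 100; the per-position
#' argmin window scores 0. Windows containing `N` are not scorable and
#' return `NA` with a warning.
#'
#' @param window Character vector of windows, each of the matrix width.
#' @param matrix A `freq_matrix`.
#' @return Numeric vector of consensus values in `[0, 100]` (or `NA`).
#' @export
consensus_value <- function(window, matrix) {
  stopifnot(inherits(matrix, "freq_matrix"))
  window <- toupper(window)
  if (any(nchar(window) != matrix$width)) {
    abort("window length must equal matrix width")
  }
  has_n <- grepl("N", window, fixed = TRUE)
  if (any(has_n)) warn("window containing N skipped (consensus value NA)")
  smin <- sum(apply(matrix$freqs, 1, min))
  smax <- sum(apply(matrix$freqs, 1, max))
  base_idx <- c(A = 1L, C = 2L, G = 3L, T = 4L)
  cv <- vapply(window, function(w) {
    b <- strsplit(w, "", fixed = TRUE)[[1]]
    s <- sum(matrix$freqs[cbind(seq_len(matrix$width), base_idx[b])])
    100 * (s - smin) / (smax - smin)
  }, numeric(1), USE.NAMES = FALSE)
  cv[has_n] <- NA_real_
  cv
}

#' Per-position argmax (consensus) window of a matrix
#'
#' Ties resolve to the first base in A, C, G, T order.
#' @param matrix A `freq_matrix`.
#' @return Single consensus window string (consensus value 100).
#' @export
consensus_window <- function(matrix) {
  paste(colnames(matrix$freqs)[apply(matrix$freqs, 1, which.max)],
        collapse = "")
}

#' Per-position argmin (anti-consensus) window of a matrix
#'
#' @param matrix A `freq_matrix`.
#' @return Single window string with consensus value 0.
#' @export
anti_consensus_window <- function(matrix) {
  paste(colnames(matrix$freqs)[apply(matrix$freqs, 1, which.min)],
        collapse = "")
}

#' Stacked per-position base-frequency plot of a matrix
#'
#' @param object A `freq_matrix`.
#' @param ... Unused.
#' @method autoplot freq_matrix
#' @export
autoplot.freq_matrix <- function(object, ...) {
  df <- as_tibble(object$freqs) |>
    mutate(position = row_number()) |>
    tidyr::pivot_longer(c("A", "C", "G", "T"), names_to = "base",
                        values_to = "frequency")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$frequency,
                                   fill = .data$base)) +
    ggplot2::geom_col(position = "stack", width = 0.85) +
    ggplot2::scale_x_continuous(breaks = seq_len(object$width)) +
    ggplot2::labs(title = object$name, x = "position", y = "base frequency") +
    ggplot2::theme_minimal()
}
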
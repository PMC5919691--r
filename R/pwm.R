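#' Construct a position weight matrix
#'
#' Normalises a 4 x W base frequency or count matrix (rows A, C, G, T) to
#' column sums of 1 after adding a pseudocount, and records the consensus
#' (per-column argmax) string.
#'
#' @param name motif name.
#' @param matrix 4 x W numeric matrix with rownames A, C, G, T (any row
#'   order); counts or frequencies.
#' @param pseudocount added to every cell before normalisation
#'   (default 0.01).
#' @return object of class `pwm`: list(name, matrix, width, consensus).
#' @export
pwm <- function(name, matrix, pseudocount = 0.01) {
  stopifnot(is.matrix(matrix), nrow(matrix) == 4L, ncol(matrix) >= 4L,
            all(matrix >= 0), !is.null(rownames(matrix)),
            setequal(rownames(matrix), c("A", "C", "G", "T")))
  m <- matrix[c("A", "C", "G", "T"), , drop = FALSE] + pseudocount
  m <- sweep(m, 2L, colSums(m), "/")
  structure(list(name = name, matrix = m, width = ncol(m),
                 consensus = paste(rownames(m)[apply(m, 2L, which.max)],
                                   collapse = "")),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("PWM '%s' (%d bp), consensus %s\n", x$name, x$width,
              x$consensus))
  invisible(x)
}

#' Read a PWM from a plain-text matrix file
#'
#' Accepts either a bare 4 x W whitespace-separated matrix (rows in A, C,
#' G, T order) or a JASPAR-style record whose four lines start with the
#' base letter, e.g. `A [ 3 10 ... ]`.
#'
#' @param path file path.
#' @param name motif name; defaults to the file stem or the JASPAR header.
#' @return a [pwm()] object.
#' @export
read_pwm <- function(path, name = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  header <- grepl("^>", lines[1L])
  if (header) {
    if (is.null(name)) name <- sub("^>\\s*", "", lines[1L])
    lines <- lines[-1L]
  }
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  stopifnot(length(lines) == 4L)
  lettered <- all(grepl("^[ACGT]", toupper(trimws(lines))))
  rows <- lapply(lines, function(l) {
    l <- gsub("[][]", " ", l)
    toks <- strsplit(trimws(l), "\\s+")[[1L]]
    if (lettered) toks <- toks[-1L]
    as.numeric(toks)
  })
  m <- do.call(rbind, rows)
  rownames(m) <- if (lettered) {
    toupper(substr(trimws(lines), 1L, 1L))
  } else c("A", "C", "G", "T")
  pwm(name, m)
}

#' Reverse complement of a PWM
#'
#' @param x a [pwm()] object.
#' @return a `pwm` scoring matches of `x` on the opposite strand.
#' @export
pwm_revcomp <- function(x) {
  stopifnot(inherits(x, "pwm"))
  m <- x$matrix[c("T", "G", "C", "A"), rev(seq_len(x$width)), drop = FALSE]
  rownames(m) <- c("A", "C", "G", "T")
  # already normalised; pseudocount 0 keeps the matrix untouched
  pwm(paste0(x$name, "_rc"), m, pseudocount = 0)
}

#' Min-max normalised PWM similarity of a sequence window
#'
#' `score = (raw - min) / (max - min)` where `raw` is the sum over
#' positions of the frequency of the observed base, and `min`/`max` sum
#' the column minima/maxima.  The score is 1 exactly on maximal-frequency
#' paths (the consensus) and 0 on minimal paths.  `N` bases contribute the
#' background frequency 0.25.
#'
#' @param x a [pwm()] object.
#' @param window character scalar of length equal to the PWM width
#'   (bases A/C/G/T/N).
#' @return similarity score in `[0, 1]`.
#' @export
pwm_similarity <- function(x, window) {
  stopifnot(inherits(x, "pwm"))
  if (nchar(window) != x$width) {
    stop("window length ", nchar(window), " does not match PWM width ",
         x$width, call. = FALSE)
  }
  code <- match(strsplit(toupper(window), "")[[1L]],
                c("A", "C", "G", "T"))
  v <- x$matrix[cbind(code, seq_len(x$width))]
  v[is.na(code)] <- 0.25
  lo <- sum(apply(x$matrix, 2L, min))
  hi <- sum(apply(x$matrix, 2L, max))
  (sum(v) - lo) / (hi - lo)
}

# Internal: similarity at every start position of an encoded sequence.
# code: integer vector (A=1..T=4, NA for other), one entry per base.
pwm_scores_all <- function(x, code) {
  W <- x$width
  n <- length(code) - W + 1L
  if (n < 1L) return(numeric(0))
  raw <- numeric(n)
  idx <- seq_len(n)
  for (j in seq_len(W)) {
    v <- x$matrix[cbind(code[idx + j - 1L], j)]
    v[is.na(v)] <- 0.25
    raw <- raw + v
  }
  lo <- sum(apply(x$matrix, 2L, min))
  hi <- sum(apply(x$matrix, 2L, max))
  (raw - lo) / (hi - lo)
}

# Internal: Pearson correlation of two PWM columns with degenerate-column
# conventions (both constant: 1 if equal, else 0; one constant: 0).
pwm_col_cor <- function(x, y) {
  sx <- sd(x); sy <- sd(y)
  if (sx < 1e-12 && sy < 1e-12) {
    return(as.numeric(max(abs(x - y)) < 1e-9))
  }
  if (sx < 1e-12 || sy < 1e-12) return(0)
  cor(x, y)
}

#' Match a query PWM against a motif library
#'
#' Similarity between two PWMs is the best mean column-wise Pearson
#' correlation over all ungapped alignments on both strands with at least
#' `min_overlap` overlapping columns.
#'
#' @param query a [pwm()] object of width at least 4.
#' @param library list of [pwm()] objects.
#' @param min_overlap minimum overlapping columns per alignment.
#' @return data.frame ranked by descending similarity: motif, similarity,
#'   offset (query column 1 minus library column 1 at the best alignment),
#'   strand.
#' @export
match_motif_to_library <- function(query, library, min_overlap = 4L) {
  stopifnot(inherits(query, "pwm"))
  if (query$width < 4L) stop("query PWM width must be >= 4", call. = FALSE)
  if (!length(library)) stop("motif library is empty", call. = FALSE)
  score_pair <- function(qm, lm) {
    wq <- ncol(qm); wl <- ncol(lm)
    best <- -Inf; best_off <- NA_integer_
    for (off in seq(-(wq - min_overlap), wl - min_overlap)) {
      qcols <- seq_len(wq)
      lcols <- qcols + off
      keep <- lcols >= 1L & lcols <= wl
      if (sum(keep) < min_overlap) next
      cc <- mapply(function(a, b) pwm_col_cor(qm[, a], lm[, b]),
                   qcols[keep], lcols[keep])
      s <- mean(cc)
      if (s > best) { best <- s; best_off <- off }
    }
    c(similarity = best, offset = best_off)
  }
  rows <- lapply(library, function(lib) {
    fwd <- score_pair(query$matrix, lib$matrix)
    rev <- score_pair(query$matrix, pwm_revcomp(lib)$matrix)
    if (fwd["similarity"] >= rev["similarity"]) {
      data.frame(motif = lib$name, similarity = fwd["similarity"],
                 offset = fwd["offset"], strand = "+",
                 stringsAsFactors = FALSE)
    } else {
      data.frame(motif = lib$name, similarity = rev["similarity"],
                 offset = rev["offset"], strand = "-",
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$similarity), , drop = FALSE]
  rownames(out) <- NULL
  out
}
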
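# Independent brute-force oracles used across the suite.  Each is a
# deliberately naive reimplementation (nested loops, per-position string
# work) kept free of the package's vectorised code paths.

oracle_revcomp <- function(s) {
  map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(map[strsplit(s, "")[[1L]]]), collapse = "")
}

# all PWM hits above sim_min on both strands, by scoring every window
# with per-window arithmetic
oracle_pwm_hits <- function(x, sequence, sim_min) {
  W <- x$width
  n <- nchar(sequence)
  lo <- sum(apply(x$matrix, 2L, min))
  hi <- sum(apply(x$matrix, 2L, max))
  score_win <- function(m, win) {
    b <- strsplit(win, "")[[1L]]
    raw <- 0
    for (j in seq_len(W)) {
      f <- if (b[j] %in% rownames(m)) m[b[j], j] else 0.25
      raw <- raw + f
    }
    (raw - lo) / (hi - lo)
  }
  mrc <- x$matrix[c("T", "G", "C", "A"), rev(seq_len(W)), drop = FALSE]
  rownames(mrc) <- c("A", "C", "G", "T")
  rows <- list()
  for (s in 0:(n - W)) {
    win <- substr(sequence, s + 1L, s + W)
    for (str in c("+", "-")) {
      m <- if (str == "+") x$matrix else mrc
      sc <- score_win(m, win)
      if (sc > sim_min) {
        rows[[length(rows) + 1L]] <- data.frame(
          start = s, end = s + W, strand = str, similarity = sc,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(start = integer(), end = integer(),
                      strand = character(), similarity = numeric()))
  }
  do.call(rbind, rows)
}

# every half-site pair with in-range spacer, by nested position loops
oracle_dimer_sites <- function(sequence, half = "AACAA",
                               smin = 4L, smax = 16L) {
  n <- nchar(sequence)
  h <- nchar(half)
  rc <- oracle_revcomp(half)
  rows <- list()
  for (p in 0:(n - h)) {
    if (substr(sequence, p + 1L, p + h) != half) next
    for (ln in smin:smax) {
      q <- p + h + ln
      if (q + h > n) next
      if (substr(sequence, q + 1L, q + h) == rc) {
        rows[[length(rows) + 1L]] <- data.frame(start = p,
                                                end = q + h,
                                                spacer = ln)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(start = integer(), end = integer(),
                      spacer = integer()))
  }
  do.call(rbind, rows)
}

# windowed local maxima by an explicit per-position loop
oracle_summits <- function(coverage, window, min_height = 15,
                           p_max = 0.05) {
  n <- length(coverage)
  lambda <- mean(coverage)
  out <- integer(0)
  for (i in seq_len(n)) {
    if (coverage[i] <= min_height) next
    ok <- TRUE
    for (j in max(1L, i - window):min(n, i + window)) {
      if (j == i) next
      if (j < i && coverage[j] >= coverage[i]) { ok <- FALSE; break }
      if (j > i && coverage[j] > coverage[i]) { ok <- FALSE; break }
    }
    if (ok && ppois(coverage[i] - 1, lambda, lower.tail = FALSE) < p_max) {
      out <- c(out, i - 1L)
    }
  }
  out
}

# all-pairs site/peak support flags
oracle_link <- function(mids, summits, max_dist) {
  vapply(mids, function(m) {
    any(abs(m - summits) < max_dist)
  }, logical(1L))
}

# all-pairs same-gene SGBR join
oracle_sgbr <- function(sox9, gli, max_interpeak) {
  rows <- list()
  for (i in seq_len(nrow(sox9))) {
    for (j in seq_len(nrow(gli))) {
      if (sox9$gene_id[i] == gli$gene_id[j] &&
          abs(sox9$summit[i] - gli$summit[j]) < max_interpeak) {
        rows[[length(rows) + 1L]] <- data.frame(
          gene_id = sox9$gene_id[i], sox9_summit = sox9$summit[i],
          gli_summit = gli$summit[j], stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(gene_id = character(), sox9_summit = integer(),
                      gli_summit = integer()))
  }
  do.call(rbind, rows)
}

# small annotation fixture built directly (not via the generator)
toy_annotation <- function(tss_positions, strands = NULL,
                           chrom_length = max(tss_positions) + 5000L) {
  n <- length(tss_positions)
  if (is.null(strands)) strands <- rep("+", n)
  start <- ifelse(strands == "+", tss_positions, tss_positions - 1999L)
  end <- start + 2000L
  prom <- phasegrn:::promoter_interval(tss_positions, strands,
                                       chrom_length = chrom_length)
  genes <- data.frame(
    gene_id = sprintf("t%02d", seq_len(n)), chrom = "chrS",
    start = as.integer(start), end = as.integer(end), strand = strands,
    tss = as.integer(tss_positions),
    promoter_start = prom[, "start"], promoter_end = prom[, "end"],
    intergenic_start = as.integer(c(0L, end[-n])),
    intergenic_end = as.integer(c(start[-1L], chrom_length)),
    stringsAsFactors = FALSE)
  structure(list(genes = genes,
                 introns = data.frame(gene_id = character(),
                                      start = integer(), end = integer(),
                                      stringsAsFactors = FALSE),
                 chrom = "chrS", chrom_length = chrom_length),
            class = "gene_annotation")
}

random_seq <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# small shared dataset for pipeline-level tests (cached per session)
small_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_dataset(sim_config(seed = 7L, n_genes = 40L,
                                            chrom_length = 3e5))
    }
    cache
  }
})
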
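test_that("PWM similarity is min-max normalised and matches column sums", {
  p <- example_pwms()$SOX9
  expect_equal(pwm_similarity(p, p$consensus), 1.0)
  # minimal path: pick the least-frequent base at every position
  worst <- paste(rownames(p$matrix)[apply(p$matrix, 2L, which.min)],
                 collapse = "")
  expect_equal(pwm_similarity(p, worst), 0.0)
  expect_error(pwm_similarity(p, "ACGT"), "width")
  # brute-force column-sum oracle on random windows
  set.seed(31)
  lo <- sum(apply(p$matrix, 2L, min))
  hi <- sum(apply(p$matrix, 2L, max))
  for (i in 1:25) {
    win <- random_seq(p$width)
    raw <- sum(vapply(seq_len(p$width), function(j)
      p$matrix[substr(win, j, j), j], numeric(1L)))
    expect_equal(pwm_similarity(p, win), (raw - lo) / (hi - lo))
  }
  # N scores as background 0.25
  winN <- paste0("N", substr(p$consensus, 2, p$width))
  rawN <- 0.25 + sum(vapply(2:p$width, function(j)
    p$matrix[substr(p$consensus, j, j), j], numeric(1L)))
  expect_equal(pwm_similarity(p, winN), (rawN - lo) / (hi - lo))
})

test_that("conserved-site scanning recovers planted sites and honours filters", {
  p <- example_pwms()$SOX9
  ann <- toy_annotation(c(3000L, 12000L))
  set.seed(12)
  n <- ann$chrom_length
  s <- random_seq(n)
  plant_at <- 2500L  # inside the first promoter
  substr(s, plant_at + 1L, plant_at + p$width) <- p$consensus
  cons <- rep(500, n)
  hits <- scan_conserved_sites(p, s, cons, ann)
  planted_hit <- hits[hits$start == plant_at & hits$strand == "+", ]
  expect_equal(nrow(planted_hit), 1L)
  expect_equal(planted_hit$similarity, 1.0)
  expect_equal(planted_hit$gene_id, "t01")
  expect_equal(planted_hit$region, "promoter")
  # conservation below the cut-off suppresses the site
  lowcons <- rep(100, n)
  hits_low <- scan_conserved_sites(p, s, lowcons, ann)
  expect_equal(nrow(hits_low), 0L)
  # minus-strand planting is found at the same interval with strand '-'
  s2 <- random_seq(n)
  substr(s2, plant_at + 1L, plant_at + p$width) <-
    oracle_revcomp(p$consensus)
  hits2 <- scan_conserved_sites(p, s2, cons, ann)
  m <- hits2[hits2$start == plant_at, ]
  expect_true("-" %in% m$strand)
  expect_error(
    scan_conserved_sites(p, s, cons,
                         generate_gene_models(sim_config(n_genes = 0L))),
    "empty")
})

test_that("scanning the TSS window drops distal matches", {
  p <- example_pwms()$GLI
  ann <- toy_annotation(2000L, chrom_length = 40000L)
  s <- random_seq(40000L, seed = 77)
  far <- 25000L   # 23 kb from the only TSS
  substr(s, far + 1L, far + p$width) <- p$consensus
  near <- 6000L   # 4 kb away
  substr(s, near + 1L, near + p$width) <- p$consensus
  hits <- scan_conserved_sites(p, s, rep(600, 40000L), ann,
                               tss_window = 10000)
  expect_true(near %in% hits$start)
  expect_false(far %in% hits$start)
})

test_that("scanner equals the exhaustive oracle and is strand symmetric", {
  p <- example_pwms()$SOX9
  set.seed(55)
  for (i in 1:10) {
    s <- random_seq(300)
    ann <- toy_annotation(150L, chrom_length = 400L)
    hits <- scan_conserved_sites(p, s, rep(600, 400L), ann,
                                 sim_min = 0.6, tss_window = 400)
    oracle <- oracle_pwm_hits(p, s, sim_min = 0.6)
    key <- function(d) sort(paste(d$start, d$strand))
    expect_equal(key(hits), key(oracle))
    # strand symmetry: hits on revcomp(s) mirror the coordinates
    s_rc <- oracle_revcomp(s)
    hits_rc <- scan_conserved_sites(p, s_rc, rep(600, 400L), ann,
                                    sim_min = 0.6, tss_window = 400)
    mirrored <- sort(paste(nchar(s) - hits$end,
                           ifelse(hits$strand == "+", "-", "+")))
    expect_equal(key(hits_rc), mirrored)
  }
})

test_that("dimer enumeration reports all spacer-compatible pairs", {
  one <- paste0("GG", "AACAA", "TCTGAAT", "TTGTT", "GG")
  d <- find_dimer_sites(one)
  expect_equal(nrow(d), 1L)
  expect_equal(d$spacer, 7L)
  expect_equal(d$start, 2L)
  expect_equal(nrow(find_dimer_sites(random_seq(200, seed = 3))), 0L)
  # overlapping first half-sites are all reported
  two <- paste0("AACAAAACAA", "GGGG", "TTGTT")
  d2 <- find_dimer_sites(two)
  expect_setequal(d2$spacer, c(9L, 4L))
  # out-of-range spacers are skipped
  short <- paste0("AACAA", "GGG", "TTGTT")
  expect_equal(nrow(find_dimer_sites(short)), 0L)
  expect_equal(nrow(find_dimer_sites(short, spacer_min = 3L)), 1L)
})

test_that("dimer enumeration equals the brute-force oracle on random fixtures", {
  set.seed(91)
  for (i in 1:10) {
    # AT-rich background makes half-sites common enough to exercise pairs
    s <- paste(sample(c("A", "C", "G", "T"), 600, replace = TRUE,
                      prob = c(0.4, 0.1, 0.1, 0.4)), collapse = "")
    got <- find_dimer_sites(s)
    want <- oracle_dimer_sites(s)
    expect_equal(nrow(got), nrow(want))
    expect_equal(sort(paste(got$start, got$spacer)),
                 sort(paste(want$start, want$spacer)))
  }
})

test_that("shuffling preserves composition, determinism, and changes order", {
  s <- random_seq(1000, seed = 4)
  sh <- shuffle_background(s, seed = 9)
  expect_equal(sort(strsplit(sh, "")[[1L]]), sort(strsplit(s, "")[[1L]]))
  expect_identical(sh, shuffle_background(s, seed = 9))
  expect_false(identical(sh, s))
})

test_that("word enrichment recovers planted words and is calibrated at null", {
  set.seed(14)
  fg <- replicate(50, random_seq(200))
  fg <- vapply(fg, function(s) {
    substr(s, 50, 57) <- "GATCGATC"; s
  }, character(1L), USE.NAMES = FALSE)
  bg <- replicate(50, random_seq(200))
  we <- word_enrichment(fg, bg, width = 8L)
  expect_equal(we$word[1L], "GATCGATC")
  expect_gte(we$fg_count[1L], 50L)
  # identical fg and bg: no word reaches 2-fold for w <= 8 on >= 10 kb
  same <- replicate(60, random_seq(200))
  expect_equal(nrow(word_enrichment(same, same, width = 8L)), 0L)
  # counts equal a naive sliding-window oracle on a short fixture
  fix <- random_seq(200, seed = 6)
  naive_count <- function(word, s) {
    total <- 0L
    for (str in c(s, oracle_revcomp(s))) {
      for (i in 1:(nchar(str) - nchar(word) + 1L)) {
        if (substr(str, i, i + nchar(word) - 1L) == word) total <- total + 1L
      }
    }
    total
  }
  we2 <- word_enrichment(fix, shuffle_background(fix, 2), width = 4L,
                         min_ratio = 0, top_n = 1000L)
  for (w in sample(we2$word, 10L)) {
    expect_equal(we2$fg_count[we2$word == w], naive_count(w, fix))
  }
  # ranking invariant to input order of sequences
  we3 <- word_enrichment(rev(fg), bg, width = 8L)
  expect_equal(we$word, we3$word)
})

test_that("dimer spacer enrichment flags planted lengths and is monotone", {
  fg_null <- data.frame(spacer = sample(4:16, 40, replace = TRUE))
  set.seed(23)
  bg <- data.frame(spacer = sample(4:16, 40, replace = TRUE))
  # equal rates: no spacer length significant
  res0 <- dimer_spacer_enrichment(fg_null, fg_null, 1e5, 1e5)
  expect_gt(min(res0$p_value), 0.05)
  # 100 planted spacers of length 7 against an empty background
  fg <- data.frame(spacer = rep(7L, 100L))
  none <- data.frame(spacer = integer())
  res1 <- dimer_spacer_enrichment(fg, none, 1e5, 1e5)
  expect_lt(res1$p_value[res1$spacer == 7L], 1e-5)
  expect_gt(min(res1$p_value[res1$spacer != 7L]), 0.5)
  # doubling the planted count never weakens the signal
  prev <- 1
  for (n in c(25, 50, 100, 200)) {
    p <- dimer_spacer_enrichment(data.frame(spacer = rep(7L, n)), none,
                                 1e5, 1e5)$p_value[4L]
    expect_lte(p, prev * (1 + 1e-12))
    prev <- p
  }
  expect_error(dimer_spacer_enrichment(fg, none, 1e5, 0), "positive")
})

test_that("motif library matching ranks self and reverse complements first", {
  pwms <- example_pwms()
  lib <- list(pwms$SOX9, pwms$GLI)
  hit <- match_motif_to_library(pwms$SOX9, lib)
  expect_equal(hit$motif[1L], "SOX9")
  expect_equal(hit$similarity[1L], 1.0)
  expect_equal(hit$strand[1L], "+")
  rc_query <- pwm_revcomp(pwms$GLI)
  hit2 <- match_motif_to_library(rc_query, lib)
  expect_equal(hit2$motif[1L], "GLI")
  expect_equal(hit2$similarity[1L], 1.0, tolerance = 1e-12)
  expect_equal(hit2$strand[1L], "-")
  expect_error(match_motif_to_library(pwms$SOX9, list()), "empty")
  # hand-computed similarity of two aligned 4-column PWMs
  m1 <- matrix(c(0.7, 0.1, 0.1, 0.1,
                 0.1, 0.7, 0.1, 0.1,
                 0.1, 0.1, 0.7, 0.1,
                 0.1, 0.1, 0.1, 0.7), nrow = 4,
               dimnames = list(c("A", "C", "G", "T"), NULL))
  m2 <- matrix(c(0.6, 0.2, 0.1, 0.1,
                 0.1, 0.6, 0.2, 0.1,
                 0.2, 0.1, 0.6, 0.1,
                 0.1, 0.1, 0.2, 0.6), nrow = 4,
               dimnames = list(c("A", "C", "G", "T"), NULL))
  q <- pwm("q", m1, pseudocount = 0)
  l <- pwm("l", m2, pseudocount = 0)
  manual <- mean(vapply(1:4, function(j) cor(m1[, j], m2[, j]),
                        numeric(1L)))
  got <- match_motif_to_library(q, list(l))
  # the full-overlap alignment must be among those searched; the best
  # reported similarity can only be >= the manual full-overlap value
  expect_gte(got$similarity[1L] + 1e-12, manual)
  expect_true(is.finite(got$offset[1L]))
})
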
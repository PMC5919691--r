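test_that("peak calling finds strict windowed maxima with tie-breaking", {
  # flat coverage: no strict local maximum above threshold
  expect_equal(nrow(call_peaks(rep(5, 500), 25)), 0L)
  expect_equal(nrow(call_peaks(numeric(0), 25)), 0L)
  # one triangular bump over low background
  cov <- rep(2, 1000)
  apex <- 400L
  for (d in -20:20) cov[apex + 1L + d] <- 40 - abs(d)
  pk <- call_peaks(cov, 25)
  expect_equal(nrow(pk), 1L)
  expect_equal(pk$summit, apex)
  expect_equal(pk$height, 40)
  expect_equal(pk$summit, which.max(cov) - 1L)  # argmax oracle
  # two bumps 30 bp apart with window 50: only the higher apex survives
  cov2 <- rep(2, 1000)
  for (d in -10:10) cov2[301L + d] <- 35 - abs(d)
  for (d in -10:10) cov2[331L + d] <- pmax(cov2[331L + d], 30 - abs(d))
  pk2 <- call_peaks(cov2, 50)
  expect_equal(pk2$summit, 300L)
  # with a smaller window both apexes are summits
  pk3 <- call_peaks(cov2, 20)
  expect_setequal(pk3$summit, c(300L, 330L))
  # plateau ties break to the leftmost position
  cov4 <- rep(1, 300)
  cov4[101:110] <- 40
  expect_equal(call_peaks(cov4, 25)$summit, 100L)
})

test_that("peak calling equals the per-position oracle on random tracks", {
  set.seed(40)
  for (i in 1:10) {
    cov <- rpois(800, 2)
    for (b in sample(100:700, 3)) {
      for (d in -15:15) {
        idx <- b + d
        if (idx >= 1 && idx <= 800) {
          cov[idx] <- cov[idx] + round(30 * exp(-d^2 / 60))
        }
      }
    }
    for (w in c(15L, 40L)) {
      got <- call_peaks(cov, w)
      expect_equal(got$summit, oracle_summits(cov, w))
    }
  }
})

test_that("summit spacing and min-height monotonicity hold", {
  set.seed(50)
  ds <- small_dataset()
  for (tf in names(ds$chip)) {
    w <- if (tf == "SOX9") 25L else 50L
    pk <- call_peaks(ds$chip[[tf]], w, tf_name = tf)
    if (nrow(pk) > 1L) expect_gt(min(diff(sort(pk$summit))), w)
    n_prev <- Inf
    for (h in c(5, 15, 25, 39)) {
      n_now <- nrow(call_peaks(ds$chip[[tf]], w, min_height = h))
      expect_lte(n_now, n_prev)
      n_prev <- n_now
    }
    # lowering p_max never increases the count
    expect_lte(nrow(call_peaks(ds$chip[[tf]], w, p_max = 0.001)),
               nrow(call_peaks(ds$chip[[tf]], w, p_max = 0.05)))
  }
})

test_that("peaks are assigned to nearest TSS with documented tie-breaking", {
  ann <- toy_annotation(c(5000L, 9000L))
  # inside the first gene's promoter
  pk <- data.frame(tf = "SOX9", summit = 4500L, height = 20,
                   window_bp = 25L, p_value = 0.001)
  br <- assign_peaks_to_genes(pk, ann)
  expect_equal(br$gene_id, "t01")
  expect_equal(br$region, "promoter")
  expect_equal(br$tss_distance, -500L)
  # exactly equidistant: lexicographically smaller id wins
  mid <- data.frame(tf = "SOX9", summit = 7000L, height = 20,
                    window_bp = 25L, p_value = 0.001)
  expect_equal(assign_peaks_to_genes(mid, ann)$gene_id, "t01")
  # minus-strand gene: signed distance flips orientation
  ann2 <- toy_annotation(6000L, strands = "-")
  up <- data.frame(tf = "SOX9", summit = 6400L, height = 20,
                   window_bp = 25L, p_value = 0.001)
  expect_equal(assign_peaks_to_genes(up, ann2)$tss_distance, -400L)
})

test_that("random peak assignment equals the all-pairs nearest-TSS oracle", {
  ds <- small_dataset()
  set.seed(60)
  summits <- sort(sample.int(ds$annotation$chrom_length, 50L) - 1L)
  pk <- data.frame(tf = "SOX9", summit = summits, height = 20,
                   window_bp = 25L, p_value = 0.001)
  br <- assign_peaks_to_genes(pk, ds$annotation)
  genes <- ds$annotation$genes
  for (i in seq_len(nrow(br))) {
    d <- abs(br$summit[i] - genes$tss)
    cands <- genes$gene_id[d == min(d)]
    expect_equal(br$gene_id[i], min(cands))
  }
})

test_that("site-peak linkage uses a strict distance rule", {
  sites <- data.frame(start = c(1000L, 1495L, 2000L),
                      end = c(1010L, 1505L, 2010L))
  peaks <- data.frame(summit = c(1005L, 1750L))
  linked <- link_sites_to_peaks(sites, peaks, max_dist = 250)
  # midpoints: 1005 (at a summit), 1500 (250 away: excluded), 2005 (255)
  expect_equal(linked$peak_supported, c(TRUE, FALSE, FALSE))
  expect_equal(linked$peak_distance, c(0L, 250L, 255L))
  # all-pairs oracle on a random fixture
  set.seed(70)
  s2 <- data.frame(start = sample.int(10000, 20L), end = NA_integer_)
  s2$end <- s2$start + 10L
  p2 <- data.frame(summit = sample.int(10000, 10L))
  got <- link_sites_to_peaks(s2, p2, max_dist = 300)
  want <- oracle_link((s2$start + s2$end) %/% 2L, p2$summit, 300)
  expect_equal(got$peak_supported, want)
})

test_that("SGBR join requires same gene and strict inter-peak distance", {
  sox <- data.frame(tf = "SOX9", summit = c(1000L, 5000L),
                    gene_id = c("ga", "gb"),
                    region = c("promoter", "intron"),
                    tss_distance = c(0L, 10L), height = 20,
                    p_value = 0.01, stringsAsFactors = FALSE)
  gli <- data.frame(tf = "GLI1", summit = c(1040L, 5400L),
                    gene_id = c("ga", "gb"),
                    region = c("promoter", "intron"),
                    tss_distance = c(40L, 410L), height = 20,
                    p_value = 0.01, stringsAsFactors = FALSE)
  expect_equal(find_sgbr(sox, gli, 50)$gene_id, "ga")
  expect_equal(nrow(find_sgbr(sox, gli, 40)), 0L)  # distance 40, strict
  # same distance but different genes: no SGBR
  gli2 <- gli
  gli2$gene_id <- c("gb", "ga")
  expect_equal(nrow(find_sgbr(sox, gli2, 50)), 0L)
  # monotone in the threshold and always a subset of SBR-and-GBR genes
  big <- find_sgbr(sox, gli, 500)
  expect_true(all(sgbr_genes(find_sgbr(sox, gli, 50)) %in%
                    sgbr_genes(big)))
  expect_true(all(sgbr_genes(big) %in%
                    intersect(sox$gene_id, gli$gene_id)))
})

test_that("SGBR join equals the all-pairs brute-force oracle", {
  set.seed(80)
  genes <- sprintf("g%02d", 1:12)
  mk <- function(tf) data.frame(
    tf = tf, summit = sample.int(50000, 30L),
    gene_id = sample(genes, 30L, replace = TRUE),
    region = sample(c("promoter", "intron", "intergenic"), 30L,
                    replace = TRUE),
    tss_distance = sample(-5000:5000, 30L), height = 20, p_value = 0.01,
    stringsAsFactors = FALSE)
  sox <- mk("SOX9"); gli <- mk("GLI3")
  for (th in c(50, 250, 1000)) {
    got <- find_sgbr(sox, gli, th)
    want <- oracle_sgbr(sox, gli, th)
    expect_equal(nrow(got), nrow(want))
    if (nrow(got)) {
      expect_setequal(paste(got$gene_id, got$sox9_summit, got$gli_summit),
                      paste(want$gene_id, want$sox9_summit,
                            want$gli_summit))
    }
  }
})

test_that("planted summits are recovered on synthetic coverage", {
  ds <- small_dataset()
  for (tf in names(ds$chip)) {
    w <- if (tf == "SOX9") 25L else 50L
    pk <- call_peaks(ds$chip[[tf]], w, tf_name = tf)
    centers <- ds$truth$peaks$center[ds$truth$peaks$tf == tf]
    # every planted center yields exactly one summit within +/- w/2
    hits <- vapply(centers, function(c0)
      sum(abs(pk$summit - c0) <= w / 2), integer(1L))
    expect_true(all(hits == 1L))
    # and no summit strays farther than the window from all centers
    strays <- vapply(pk$summit, function(s)
      min(abs(s - centers)) > w, logical(1L))
    expect_false(any(strays))
  }
})
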
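test_that("gene models are non-overlapping, in bounds, and tile the gaps", {
  cfg <- sim_config(seed = 1L, n_genes = 50L, chrom_length = 1e6)
  ann <- generate_gene_models(cfg)
  g <- ann$genes
  expect_equal(nrow(g), 50L)
  # O(n^2) all-pairs interval-overlap oracle on gene bodies
  for (i in seq_len(nrow(g) - 1L)) {
    for (j in (i + 1L):nrow(g)) {
      expect_true(g$end[i] <= g$start[j] || g$end[j] <= g$start[i])
    }
  }
  expect_true(all(g$promoter_start >= 0))
  expect_true(all(g$promoter_end <= cfg$chrom_length))
  # intergenic bounds tile the gaps between adjacent bodies
  o <- order(g$start)
  expect_equal(g$intergenic_end[o][-50L], g$start[o][-1L])
  expect_equal(g$intergenic_start[o][-1L], g$end[o][-50L])
  # introns lie inside their gene's body
  ints <- merge(ann$introns, g[, c("gene_id", "start", "end")],
                by = "gene_id", suffixes = c("", "_gene"))
  expect_true(all(ints$start >= ints$start_gene & ints$end <= ints$end_gene))
})

test_that("gene model generation handles the empty and infeasible cases", {
  ann <- generate_gene_models(sim_config(n_genes = 0L))
  expect_equal(nrow(ann$genes), 0L)
  expect_equal(nrow(ann$introns), 0L)
  expect_error(
    generate_gene_models(sim_config(n_genes = 100L, chrom_length = 5e4)),
    "too small")
})

test_that("the five generators are byte-identical under a fixed seed", {
  cfg <- sim_config(seed = 11L, n_genes = 15L, chrom_length = 1.5e5)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(d1$annotation, d2$annotation)
  expect_identical(d1$sequence, d2$sequence)
  expect_identical(d1$conservation, d2$conservation)
  expect_identical(d1$chip, d2$chip)
  expect_identical(d1$expression, d2$expression)
  expect_identical(d1$truth, d2$truth)
})

test_that("planted sites appear verbatim in the sequence", {
  cfg <- sim_config(seed = 3L, n_genes = 6L, chrom_length = 8e4)
  ann <- generate_gene_models(cfg)
  ids <- ann$genes$gene_id
  cfg$motif_plan <- list(
    list(tf = "SOX9", type = "dimer", gene_id = ids[1L],
         region = "promoter", strand = "+", spacer = 7L,
         conserved = TRUE, chip_tfs = character()),
    list(tf = "SOX9", type = "monomer", consensus = "AACAAT",
         gene_id = ids[2L], region = "promoter", strand = "-",
         conserved = TRUE, chip_tfs = "SOX9"),
    list(tf = "GLI1", type = "monomer", consensus = "GACCACCCA",
         gene_id = ids[3L], region = "intron", strand = "+",
         conserved = FALSE, chip_tfs = character()))
  pl <- plant_motifs_and_sequence(ann, cfg)
  s <- pl$sites
  expect_equal(nrow(s), 3L)
  dimer <- s[s$type == "dimer", ]
  frag <- substr(pl$sequence, dimer$start + 1L, dimer$end)
  expect_equal(nchar(frag), 17L)  # 5 + 7 + 5
  expect_equal(substr(frag, 1, 5), "AACAA")
  expect_equal(substr(frag, 13, 17), "TTGTT")
  minus <- s[s$strand == "-" & s$type == "monomer", ]
  expect_equal(substr(pl$sequence, minus$start + 1L, minus$end),
               oracle_revcomp("AACAAT"))
  plus <- s[s$tf == "GLI1", ]
  expect_equal(substr(pl$sequence, plus$start + 1L, plus$end),
               "GACCACCCA")
  # intron placement respected
  ints <- ann$introns[ann$introns$gene_id == ids[3L], ]
  expect_true(any(plus$start >= ints$start & plus$end <= ints$end))
})

test_that("an empty plan yields pure background with no recorded sites", {
  cfg <- sim_config(seed = 5L, n_genes = 4L, chrom_length = 6e4,
                    motif_plan = list())
  ann <- generate_gene_models(cfg)
  pl <- plant_motifs_and_sequence(ann, cfg)
  expect_equal(nrow(pl$sites), 0L)
  expect_equal(nchar(pl$sequence), cfg$chrom_length)
})

test_that("conservation has the configured background mean and elevated sites", {
  cfg <- sim_config(seed = 9L, n_genes = 4L, chrom_length = 5e4,
                    motif_plan = list())
  empty_sites <- data.frame(start = integer(), end = integer(),
                            conserved = logical())
  cons <- simulate_conservation(empty_sites, cfg)
  se <- cfg$cons_background_sd / sqrt(cfg$chrom_length)
  expect_lt(abs(mean(cons) - cfg$cons_background_mean), 3 * se + 0.5)
  one <- data.frame(start = 1000L, end = 1010L, conserved = TRUE)
  cons2 <- simulate_conservation(one, cfg)
  expect_gt(min(cons2[1001:1010]), 300)
  expect_identical(cons2, simulate_conservation(one, cfg))
})

test_that("ChIP coverage is Poisson background plus bumps at planted centers", {
  cfg <- sim_config(seed = 13L, n_genes = 4L, chrom_length = 5e4,
                    chip_peak_height = 40, chip_peak_sd = 50)
  none <- data.frame(tf = character(), gene_id = character(),
                     center = integer(), cobound = logical())
  cov0 <- simulate_chip_coverage(none, "SOX9", cfg)
  se <- sqrt(cfg$chip_lambda_bg / cfg$chrom_length)
  expect_lt(abs(mean(cov0) - cfg$chip_lambda_bg), 4 * se)
  one <- data.frame(tf = "SOX9", gene_id = "g1", center = 20000L,
                    cobound = FALSE)
  cov1 <- simulate_chip_coverage(one, "SOX9", cfg)
  expect_lt(abs(which.max(cov1) - 1L - 20000L), cfg$chip_peak_sd)
  expect_identical(cov1, simulate_chip_coverage(one, "SOX9", cfg))
})

test_that("expression realises cluster shapes exactly at zero noise", {
  cfg <- sim_config(seed = 2L, n_genes = 20L, chrom_length = 2e5,
                    replicate_sd = 0)
  ds <- simulate_dataset(cfg)
  zm <- expr_zone_means(ds$expression)
  for (i in seq_len(nrow(ds$truth$genes))) {
    cl <- ds$truth$genes$cluster[i]
    expect_equal(unname(zm[ds$truth$genes$gene_id[i], ]),
                 unname(cfg$zone_mean_profiles[cl, ]))
  }
  g1 <- zm[ds$truth$genes$gene_id[ds$truth$genes$cluster == "I"][1L], ]
  expect_true(all(diff(g1) < 0))
})

test_that("noisy expression means converge to configured profiles", {
  cfg <- sim_config(seed = 21L, n_genes = 30L, chrom_length = 2.5e5,
                    replicate_sd = 30, n_replicates = 12L)
  ds <- simulate_dataset(cfg)
  zm <- expr_zone_means(ds$expression)
  tol <- 3 * cfg$replicate_sd / sqrt(cfg$n_replicates)
  for (i in seq_len(nrow(ds$truth$genes))) {
    expected <- cfg$zone_mean_profiles[ds$truth$genes$cluster[i], ]
    expect_true(all(abs(zm[ds$truth$genes$gene_id[i], ] - expected) < tol))
  }
})

test_that("ground truth is recoverable from the emitted artifacts alone", {
  ds <- small_dataset()
  # planted sequences findable by exhaustive string search
  mono <- ds$truth$sites[ds$truth$sites$type == "monomer", ]
  for (i in seq_len(min(nrow(mono), 10L))) {
    frag <- substr(ds$sequence, mono$start[i] + 1L, mono$end[i])
    fwd <- if (mono$strand[i] == "+") frag else oracle_revcomp(frag)
    expect_true(fwd %in% c("AACAAT", "GACCACCCA"))
  }
  # peak centers recoverable by local coverage argmax
  pk <- ds$truth$peaks
  for (i in seq_len(min(nrow(pk), 10L))) {
    cov <- ds$chip[[pk$tf[i]]]
    win <- (pk$center[i] - 100L):(pk$center[i] + 100L)
    local_max <- win[which.max(cov[win + 1L])]
    expect_lt(abs(local_max - pk$center[i]), 25L)
  }
  # cluster shapes recoverable by zone-mean argmax (noiseless profile peaks)
  zm <- expr_zone_means(ds$expression)
  cl <- ds$truth$genes$cluster
  peak_zone <- colnames(zm)[apply(zm[ds$truth$genes$gene_id, ], 1L,
                                  which.max)]
  expected <- c(I = "PZ", II = "PHZ", III = "UHZ", IV = "LHZ")[cl]
  expect_gt(mean(peak_zone == expected), 0.9)
})
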
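#' Configuration for the synthetic growth-plate dataset generator
#'
#' Collects and validates every tunable of the synthetic-data module.  The
#' defaults describe the study conditions the pipeline is verified under:
#' four phase clusters with proportions matching the zonal differential
#' expression library (cluster I decreasing from PZ, II peaking in PHZ, III
#' in UHZ, IV in LHZ), triplicate linear-scale expression values in the
#' hundreds (RMA-intensity-like, commensurate with On/Off reference levels
#' of a few hundred), conservation on the 0-1000 phastCons-like scale with
#' planted sites well above the 300 cut-off, and Poisson ChIP background
#' with Gaussian-shaped peaks clearing the height-15 peak filter.
#'
#' @param seed integer seed governing every random draw.
#' @param chrom_length chromosome length in bp (one chromosome, "chrS").
#' @param n_genes number of genes to place.
#' @param cluster_fractions proportions of genes in phase clusters I-IV;
#'   must sum to 1.  Default 654:299:31:907 (the four cluster sizes among
#'   1891 phasic genes).
#' @param zone_mean_profiles 4x4 numeric matrix, rows = clusters I-IV,
#'   columns = zones PZ,PHZ,UHZ,LHZ, giving mean expression per zone.  The
#'   rows must realise the four phasic shapes (I strictly decreasing,
#'   II/III/IV peaking in PHZ/UHZ/LHZ).
#' @param replicate_sd replicate noise standard deviation (expression units).
#' @param n_replicates replicates per zone.
#' @param background_gc GC fraction of background sequence, in (0,1).
#' @param cons_background_mean,cons_site_mean conservation means (0-1000
#'   scale) for background and planted functional sites; site mean must
#'   exceed 300 for planted sites to pass the conservation filter.
#' @param cons_background_sd,cons_site_sd conservation jitter SDs; draws are
#'   clamped symmetrically at 3 SD so configured means are preserved and
#'   planted-site minima stay above `cons_site_mean - 3*cons_site_sd`.
#' @param chip_lambda_bg Poisson mean of background ChIP coverage.
#' @param chip_peak_height height of planted coverage bumps above background.
#' @param chip_peak_sd Gaussian width (bp) of planted bumps.
#' @param cobinding_fraction_phasic,cobinding_fraction_nonphasic probability
#'   that a phasic (cluster I-III) or reference (cluster IV) gene receives a
#'   SOX9+GLI co-bound locus.
#' @param max_summit_offset maximal distance (bp) between the SOX9 and GLI
#'   summits planted at a co-bound locus.
#' @param spacer_min,spacer_max dimer half-site spacer length range (bp).
#' @param motif_plan optional list of planting directives (see
#'   [plant_motifs_and_sequence()]); `NULL` means the default plan built by
#'   [simulate_dataset()] from cluster labels and co-binding flags.
#' @param gene_length_range min/max gene body length (bp).
#' @param n_replicates replicates per zone (the study used triplicates).
#' @return an object of class `sim_config` (a validated named list).
#' @export
#' @examples
#' cfg <- sim_config(seed = 1, n_genes = 20, chrom_length = 2e5)
#' cfg$cluster_fractions
sim_config <- function(seed = 42L,
                       chrom_length = 1e6,
                       n_genes = 200L,
                       cluster_fractions = c(654, 299, 31, 907) / 1891,
                       zone_mean_profiles = NULL,
                       replicate_sd = 60,
                       n_replicates = 3L,
                       background_gc = 0.42,
                       cons_background_mean = 100,
                       cons_background_sd = 30,
                       cons_site_mean = 500,
                       cons_site_sd = 25,
                       chip_lambda_bg = 2,
                       chip_peak_height = 40,
                       chip_peak_sd = 20,
                       cobinding_fraction_phasic = 0.5,
                       cobinding_fraction_nonphasic = 0.05,
                       max_summit_offset = 40L,
                       spacer_min = 4L,
                       spacer_max = 16L,
                       motif_plan = NULL,
                       gene_length_range = c(1500L, 3000L)) {
  if (is.null(zone_mean_profiles)) {
    zone_mean_profiles <- rbind(
      I   = c(1200, 900, 600, 300),
      II  = c(500, 1400, 600, 400),
      III = c(400, 600, 1300, 500),
      IV  = c(300, 400, 600, 1400))
    colnames(zone_mean_profiles) <- ZONES
  }
  check_scalar(seed, "seed", integer = TRUE)
  check_scalar(chrom_length, "chrom_length", min = 0)
  check_scalar(n_genes, "n_genes", min = 0, integer = TRUE)
  check_scalar(n_replicates, "n_replicates", min = 1, integer = TRUE)
  check_scalar(replicate_sd, "replicate_sd", min = 0)
  stopifnot(length(cluster_fractions) == 4L, all(cluster_fractions >= 0))
  if (abs(sum(cluster_fractions) - 1) > 1e-9) {
    stop("cluster_fractions must sum to 1", call. = FALSE)
  }
  stopifnot(is.matrix(zone_mean_profiles),
            all(dim(zone_mean_profiles) == c(4L, 4L)),
            all(zone_mean_profiles >= 0))
  if (background_gc <= 0 || background_gc >= 1) {
    stop("background_gc must be in (0, 1)", call. = FALSE)
  }
  # cluster shape contract: I decreasing, II-IV peak in PHZ/UHZ/LHZ
  if (any(diff(zone_mean_profiles[1L, ]) >= 0)) {
    stop("cluster I profile must be strictly decreasing PZ -> LHZ",
         call. = FALSE)
  }
  peaks <- apply(zone_mean_profiles[2:4, , drop = FALSE], 1L, which.max)
  if (!identical(unname(peaks), c(2L, 3L, 4L))) {
    stop("cluster II/III/IV profiles must peak in PHZ/UHZ/LHZ respectively",
         call. = FALSE)
  }
  stopifnot(cons_background_mean >= 0, cons_site_mean >= 0,
            cons_background_sd >= 0, cons_site_sd >= 0,
            cons_background_mean - 3 * cons_background_sd >= 0,
            cons_site_mean + 3 * cons_site_sd <= 1000)
  stopifnot(chip_lambda_bg >= 0, chip_peak_height >= 0, chip_peak_sd > 0)
  stopifnot(cobinding_fraction_phasic >= 0, cobinding_fraction_phasic <= 1,
            cobinding_fraction_nonphasic >= 0,
            cobinding_fraction_nonphasic <= 1)
  check_scalar(spacer_min, "spacer_min", min = 0, integer = TRUE)
  check_scalar(spacer_max, "spacer_max", min = spacer_min, integer = TRUE)
  stopifnot(length(gene_length_range) == 2L,
            gene_length_range[1L] >= 200L,
            gene_length_range[2L] >= gene_length_range[1L])

  structure(list(
    seed = as.integer(seed),
    chrom_length = as.integer(chrom_length),
    chrom = "chrS",
    n_genes = as.integer(n_genes),
    cluster_fractions = cluster_fractions,
    zone_mean_profiles = zone_mean_profiles,
    replicate_sd = replicate_sd,
    n_replicates = as.integer(n_replicates),
    background_gc = background_gc,
    cons_background_mean = cons_background_mean,
    cons_background_sd = cons_background_sd,
    cons_site_mean = cons_site_mean,
    cons_site_sd = cons_site_sd,
    chip_lambda_bg = chip_lambda_bg,
    chip_peak_height = chip_peak_height,
    chip_peak_sd = chip_peak_sd,
    cobinding_fraction_phasic = cobinding_fraction_phasic,
    cobinding_fraction_nonphasic = cobinding_fraction_nonphasic,
    max_summit_offset = as.integer(max_summit_offset),
    spacer_min = as.integer(spacer_min),
    spacer_max = as.integer(spacer_max),
    motif_plan = motif_plan,
    gene_length_range = as.integer(gene_length_range)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic dataset configuration\n")
  cat(sprintf("  %d genes on %s (%d bp), seed %d\n",
              x$n_genes, x$chrom, x$chrom_length, x$seed))
  cat(sprintf("  cluster fractions I-IV: %s\n",
              paste(signif(x$cluster_fractions, 3), collapse = " ")))
  cat(sprintf("  co-binding fractions: phasic %.2f, non-phasic %.2f\n",
              x$cobinding_fraction_phasic, x$cobinding_fraction_nonphasic))
  invisible(x)
}
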
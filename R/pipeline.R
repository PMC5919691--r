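#' Run the full phasic co-regulation pipeline on a dataset
#'
#' Chains every stage on an in-memory dataset (typically a `sim_dataset`,
#' or an equivalent list built from files read with the package's I/O):
#' expression phasing, conserved SOX9 motif scanning, dimer detection,
#' per-TF peak calling (25 bp window for SOX9 coverage, 50 bp for GLI
#' tracks, the respective ChIP-seq/ChIP-chip conventions), nearest-gene
#' assignment, motif-site/peak linkage, SGBR detection, co-binding
#' enrichment, and GRN assembly.
#'
#' @param ds list with elements `annotation`, `sequence`, `conservation`,
#'   `chip` (named list of coverage vectors; SOX9 track named "SOX9"),
#'   `expression`.
#' @param pwm_sox9 PWM used for SOX9 site scanning; default the built-in.
#' @param sim_min,cons_min,tss_window motif-scan thresholds (see
#'   [scan_conserved_sites()]).
#' @param window_sox9,window_gli peak-calling windows (bp).
#' @param min_height,p_max peak filters (see [call_peaks()]).
#' @param site_peak_dist motif-site/peak linkage distance (bp).
#' @param max_interpeak SGBR inter-peak distance threshold (bp).
#' @param phasic_zones grouping for the enrichment test.
#' @param csd_threshold,k,n_init,seed expression-phasing parameters.
#' @return list with `phasing`, `sites`, `dimers`, `peaks` (per TF),
#'   `regions` (per TF), `sgbr`, `contingency`, `enrichment`, `grn`.
#' @export
run_pipeline <- function(ds,
                         pwm_sox9 = example_pwms()$SOX9,
                         sim_min = 0.85, cons_min = 300,
                         tss_window = 10000,
                         window_sox9 = 25L, window_gli = 50L,
                         min_height = 15, p_max = 0.05,
                         site_peak_dist = 250,
                         max_interpeak = 250,
                         phasic_zones = c("PZ", "PHZ", "UHZ"),
                         csd_threshold = 0.15, k = 4L, n_init = 25L,
                         seed = 1L) {
  phasing <- phase_expression(ds$expression, csd_threshold = csd_threshold,
                              k = k, n_init = n_init, seed = seed)
  sites <- scan_conserved_sites(pwm_sox9, ds$sequence, ds$conservation,
                                ds$annotation, sim_min = sim_min,
                                cons_min = cons_min,
                                tss_window = tss_window)
  dimers <- find_dimer_sites(ds$sequence, annotation = ds$annotation)

  peaks <- lapply(names(ds$chip), function(tf) {
    w <- if (tf == "SOX9") window_sox9 else window_gli
    call_peaks(ds$chip[[tf]], window_bp = w, min_height = min_height,
               p_max = p_max, tf_name = tf)
  })
  names(peaks) <- names(ds$chip)
  regions <- lapply(peaks, assign_peaks_to_genes,
                    annotation = ds$annotation)

  if ("SOX9" %in% names(peaks)) {
    sites <- link_sites_to_peaks(sites, peaks$SOX9,
                                 max_dist = site_peak_dist)
  }
  gli_tfs <- grep("^GLI", names(regions), value = TRUE)
  gli_regions <- do.call(rbind, unname(regions[gli_tfs]))
  sgbr <- if (!is.null(regions$SOX9) && length(gli_tfs)) {
    find_sgbr(regions$SOX9, gli_regions, max_interpeak = max_interpeak)
  } else {
    find_sgbr(data.frame(), data.frame())
  }

  contingency <- build_contingency(phasing$degs, sgbr_genes(sgbr),
                                   phasic_zones = phasic_zones)
  enrichment <- test_contingency(contingency)

  all_regions <- do.call(rbind, unname(regions))
  grn <- assemble_grn(phasing$degs, all_regions, sgbr,
                      zone_means = expr_zone_means(ds$expression))
  list(phasing = phasing, sites = sites, dimers = dimers,
       peaks = peaks, regions = regions, sgbr = sgbr,
       contingency = contingency, enrichment = enrichment, grn = grn)
}
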
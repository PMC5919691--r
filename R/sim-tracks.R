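#' Simulate a per-base conservation track
#'
#' Background bases score around `cons_background_mean` and every base of a
#' planted site flagged `conserved` scores around `cons_site_mean`, on the
#' 0-1000 phastCons-like scale.  Gaussian jitter is clamped symmetrically at
#' three standard deviations, which preserves the configured means exactly
#' and guarantees planted-site minima stay above
#' `cons_site_mean - 3 * cons_site_sd` (above the 300 cut-off under the
#' default site mean of 500).
#'
#' @param sites planted-site table (the `sites` element of
#'   [plant_motifs_and_sequence()] output); may have zero rows.
#' @param config a [sim_config()].
#' @return integer vector of length `chrom_length` with per-base scores.
#' @export
simulate_conservation <- function(sites, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  n <- config$chrom_length
  clamp3 <- function(x, m, s) pmin(pmax(x, m - 3 * s), m + 3 * s)
  cons <- clamp3(rnorm(n, config$cons_background_mean,
                       config$cons_background_sd),
                 config$cons_background_mean, config$cons_background_sd)
  if (nrow(sites)) {
    for (i in which(sites$conserved)) {
      idx <- seq.int(sites$start[i] + 1L, sites$end[i])
      cons[idx] <- clamp3(rnorm(length(idx), config$cons_site_mean,
                                config$cons_site_sd),
                          config$cons_site_mean, config$cons_site_sd)
    }
  }
  as.integer(round(pmin(pmax(cons, 0), 1000)))
}

#' Derive planted ChIP summit positions from the ground-truth site table
#'
#' Each planted site whose `chip_tfs` field names a TF contributes one
#' summit for that TF at the site centre.  When a site names two TFs (a
#' co-bound locus) the second TF's summit is offset by a uniform draw in
#' `[-max_summit_offset, max_summit_offset]`, emulating adjacent but not
#' identical binding events.
#'
#' @param sites planted-site table.
#' @param config a [sim_config()].
#' @return data.frame: tf, gene_id, center (0-based bp), cobound (logical).
#' @export
planted_peak_centers <- function(sites, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 3L)
  out <- list()
  if (nrow(sites)) {
    for (i in seq_len(nrow(sites))) {
      tfs <- strsplit(sites$chip_tfs[i], ",", fixed = TRUE)[[1L]]
      tfs <- tfs[nzchar(tfs)]
      if (!length(tfs)) next
      center <- as.integer((sites$start[i] + sites$end[i]) %/% 2L)
      offs <- c(0L, sample(seq(-config$max_summit_offset,
                               config$max_summit_offset), length(tfs) - 1L,
                           replace = TRUE))
      out[[length(out) + 1L]] <- data.frame(
        tf = tfs, gene_id = sites$gene_id[i],
        center = pmin(pmax(center + offs, 0L),
                      config$chrom_length - 1L),
        cobound = length(tfs) > 1L, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(tf = character(), gene_id = character(),
                      center = integer(), cobound = logical(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Simulate a ChIP coverage track for one transcription factor
#'
#' Coverage is Poisson background of mean `chip_lambda_bg` plus a
#' Gaussian-shaped bump of height `chip_peak_height` and width
#' `chip_peak_sd` (bp) centred at every planted summit of the requested TF.
#'
#' @param peak_centers data.frame from [planted_peak_centers()].
#' @param tf_name TF whose track to simulate (e.g. "SOX9", "GLI1").
#' @param config a [sim_config()].
#' @return numeric vector of length `chrom_length` with per-base coverage.
#' @export
simulate_chip_coverage <- function(peak_centers, tf_name, config) {
  stopifnot(inherits(config, "sim_config"))
  # per-TF seed offset keeps tracks independent but reproducible
  set.seed(config$seed + 10L + sum(utf8ToInt(tf_name)) %% 1000L)
  n <- config$chrom_length
  cov <- as.numeric(rpois(n, config$chip_lambda_bg))
  centers <- peak_centers$center[peak_centers$tf == tf_name]
  halfw <- ceiling(4 * config$chip_peak_sd)
  for (c0 in centers) {
    idx <- seq.int(max(0L, c0 - halfw), min(n - 1L, c0 + halfw))
    cov[idx + 1L] <- cov[idx + 1L] +
      config$chip_peak_height *
      exp(-((idx - c0)^2) / (2 * config$chip_peak_sd^2))
  }
  cov
}
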
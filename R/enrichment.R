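#' Build the phasic-versus-reference SGBR contingency table
#'
#' Splits the clustered phasic genes into a phasic group (clusters whose
#' peak zone is in `phasic_zones`) and the complementary reference group
#' (by default the LHZ cluster), and counts genes with and without an
#' SGBR in each: `a` = phasic with SGBR, `b` = phasic without, `c` =
#' reference with, `d` = reference without.
#'
#' @param degs data.frame with columns `gene_id` and `cluster`
#'   ("I".."IV"), as produced by [phase_expression()].
#' @param sgbr_gene_ids character vector of genes carrying at least one
#'   SGBR (see [sgbr_genes()]).
#' @param phasic_zones zones defining the phasic group (default PZ, PHZ,
#'   UHZ, i.e. clusters I-III versus the LHZ cluster IV).
#' @return object of class `contingency_table`: list(a, b, c, d, label).
#' @export
build_contingency <- function(degs, sgbr_gene_ids,
                              phasic_zones = c("PZ", "PHZ", "UHZ")) {
  stopifnot(all(c("gene_id", "cluster") %in% names(degs)),
            !anyNA(degs$cluster))
  zone <- CLUSTER_ZONE[degs$cluster]
  phasic <- zone %in% phasic_zones
  if (!any(!phasic)) stop("reference group is empty", call. = FALSE)
  has <- degs$gene_id %in% sgbr_gene_ids
  structure(list(a = sum(phasic & has), b = sum(phasic & !has),
                 c = sum(!phasic & has), d = sum(!phasic & !has),
                 label = paste(paste(phasic_zones, collapse = "+"),
                               "vs",
                               paste(setdiff(ZONES, phasic_zones),
                                     collapse = "+"))),
            class = "contingency_table")
}

#' Fisher/odds-ratio result for a contingency table
#'
#' @param table a `contingency_table` from [build_contingency()].
#' @param method two-tailed rule passed to [fisher_exact_p()].
#' @return an `enrichment_result` (see [fisher_or()]).
#' @export
test_contingency <- function(table, method = c("mass", "doubling")) {
  stopifnot(inherits(table, "contingency_table"))
  fisher_or(table$a, table$b, table$c, table$d, method = method,
            label = table$label)
}

#' Sweep SGBR definitions over inter-peak thresholds and TSS-distance bins
#'
#' For every combination of inter-peak threshold, TSS-distance bin and
#' stratum, SGBRs are recomputed, the phasic-versus-reference table is
#' rebuilt and the Fisher/odds-ratio test rerun.  A TSS-distance bin
#' `[lo, hi)` keeps SGBRs whose SOX9 summit lies at an absolute TSS
#' distance within the bin.  The `"intergenic"` stratum keeps only SGBRs
#' whose region class is intergenic, probing long-range co-binding.  A
#' Benjamini-Hochberg column is appended for information; the headline
#' analysis applies no multiple-testing correction.
#'
#' @param degs clustered phasic gene table (`gene_id`, `cluster`).
#' @param sox9_regions,gli_regions `binding_regions` tables.
#' @param interpeak_thresholds ascending numeric vector of inter-peak
#'   distance thresholds (bp).
#' @param tss_bins list of `c(lo, hi)` absolute TSS-distance bins;
#'   default a single unbounded bin.
#' @param strata subset of `c("all", "intergenic")`.
#' @param phasic_zones passed to [build_contingency()].
#' @return data.frame: one row per (threshold, bin, stratum) with counts,
#'   both odds ratios, `fisher_p` and `p_bh`.
#' @export
enrichment_sweep <- function(degs, sox9_regions, gli_regions,
                             interpeak_thresholds = c(50, 250),
                             tss_bins = list(c(0, Inf)),
                             strata = "all",
                             phasic_zones = c("PZ", "PHZ", "UHZ")) {
  stopifnot(!is.unsorted(interpeak_thresholds),
            all(strata %in% c("all", "intergenic")))
  rows <- list()
  for (th in interpeak_thresholds) {
    sgbr <- find_sgbr(sox9_regions, gli_regions, max_interpeak = th)
    dist_lookup <- abs(sox9_regions$tss_distance[
      match(sgbr$sox9_summit, sox9_regions$summit)])
    for (bi in seq_along(tss_bins)) {
      bin <- tss_bins[[bi]]
      in_bin <- dist_lookup >= bin[1L] & dist_lookup < bin[2L]
      for (st in strata) {
        keep <- in_bin & (st == "all" | sgbr$region == "intergenic")
        tab <- build_contingency(degs, unique(sgbr$gene_id[keep]),
                                 phasic_zones)
        res <- test_contingency(tab)
        rows[[length(rows) + 1L]] <- data.frame(
          interpeak_threshold = th,
          tss_bin_lo = bin[1L], tss_bin_hi = bin[2L], stratum = st,
          a = res$a, b = res$b, c = res$c, d = res$d,
          relative_risk = res$relative_risk,
          odds_ratio = res$odds_ratio,
          fisher_p = res$fisher_p, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  out$p_bh <- p.adjust(out$fisher_p, method = "BH")
  out
}

#' Re-test co-binding enrichment under a null of equal fractions
#'
#' Calibration helper: holding the cluster structure fixed, re-draws each
#' gene's co-binding flag as Bernoulli with the same probability in the
#' phasic and reference groups, rebuilds the contingency table and
#' returns the two-tailed Fisher p-value, repeated `n_replicates` times.
#' Under this null the rejection rate at level alpha should not exceed
#' alpha (Fisher is conservative on discrete tables).
#'
#' @param degs clustered phasic gene table (`gene_id`, `cluster`).
#' @param cobinding_fraction shared co-binding probability.
#' @param n_replicates number of null replicates.
#' @param seed RNG seed.
#' @param phasic_zones passed to [build_contingency()].
#' @return numeric vector of `n_replicates` p-values.
#' @export
null_cobinding_pvalues <- function(degs, cobinding_fraction = 0.2,
                                   n_replicates = 500L, seed = 1L,
                                   phasic_zones = c("PZ", "PHZ", "UHZ")) {
  set.seed(seed)
  vapply(seq_len(n_replicates), function(i) {
    flags <- runif(nrow(degs)) < cobinding_fraction
    tab <- build_contingency(degs, degs$gene_id[flags], phasic_zones)
    fisher_exact_p(tab$a, tab$b, tab$c, tab$d)
  }, numeric(1L))
}
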
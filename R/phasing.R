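#' Coefficient of standard deviation (CSD)
#'
#' The variability statistic used to select phasic genes: the standard
#' deviation of a gene's zone means divided by their mean, `S / X̄`.  The
#' sample (n-1) standard deviation is used by default; with four zones the
#' population version differs by a factor of `sqrt(3/4)` and is available
#' via `sample_sd = FALSE`.  The statistic is scale invariant:
#' `compute_csd(c * v) == compute_csd(v)` for any `c > 0`.
#'
#' @param values numeric vector of at least two zone mean expression
#'   levels, all nonnegative.
#' @param sample_sd use the n-1 (sample) standard deviation (default) or
#'   the population standard deviation.
#' @return nonnegative CSD value.
#' @export
#' @examples
#' compute_csd(c(1, 2, 3, 4))  # 0.5164
compute_csd <- function(values, sample_sd = TRUE) {
  stopifnot(is.numeric(values), length(values) >= 2L, all(values >= 0))
  m <- mean(values)
  if (m == 0) stop("CSD undefined: mean expression is zero", call. = FALSE)
  s <- sd(values)
  if (!sample_sd) s <- s * sqrt((length(values) - 1) / length(values))
  s / m
}

#' Call On/Off expression states against reference-gene thresholds
#'
#' Derives a single global threshold from the matrix itself:
#' `T = max(` level of the On-reference gene in its Off zone (HZ, the mean
#' of UHZ and LHZ), level of the Off-reference gene in its Off zone (PZ)
#' `)`.  The On-reference is a gene expressed in PZ/PHZ and silent in
#' hypertrophy (Sox9-like); the Off-reference the converse (Col10a1-like).
#' A gene is On in a zone iff its zone mean exceeds `T`; for On/Off
#' purposes HZ is the average of the UHZ and LHZ means.  Each gene is then
#' assigned exactly one category from its (PZ, PHZ, HZ) booleans.
#'
#' @param expr expression data.frame (`gene_id` + `<zone>_<rep>` columns).
#' @param reference_on_gene,reference_off_gene gene ids of the two
#'   threshold references; both must be present in `expr`.
#' @return data.frame of class `onoff_table`: gene_id, On booleans
#'   `on_PZ`, `on_PHZ`, `on_HZ`, the threshold used, and `category` in
#'   {common, PZ-specific, PHZ-specific, HZ-specific, other-combination,
#'   all-off}.
#' @export
call_on_off <- function(expr, reference_on_gene = "sox9_like",
                        reference_off_gene = "col10a1_like") {
  zm <- expr_zone_means(expr)
  for (g in c(reference_on_gene, reference_off_gene)) {
    if (!g %in% rownames(zm)) {
      stop("reference gene not found in matrix: ", g, call. = FALSE)
    }
  }
  hz <- (zm[, "UHZ"] + zm[, "LHZ"]) / 2
  threshold <- max(hz[reference_on_gene], zm[reference_off_gene, "PZ"])
  on_pz <- zm[, "PZ"] > threshold
  on_phz <- zm[, "PHZ"] > threshold
  on_hz <- hz > threshold
  category <- onoff_category(on_pz, on_phz, on_hz)
  structure(data.frame(gene_id = rownames(zm), on_PZ = on_pz,
                       on_PHZ = on_phz, on_HZ = on_hz,
                       threshold = threshold, category = category,
                       row.names = NULL, stringsAsFactors = FALSE),
            class = c("onoff_table", "data.frame"))
}

# Category is a pure function of the three booleans.
onoff_category <- function(on_pz, on_phz, on_hz) {
  n_on <- on_pz + on_phz + on_hz
  ifelse(n_on == 3L, "common",
  ifelse(n_on == 0L, "all-off",
  ifelse(on_pz & n_on == 1L, "PZ-specific",
  ifelse(on_phz & n_on == 1L, "PHZ-specific",
  ifelse(on_hz & n_on == 1L, "HZ-specific", "other-combination")))))
}

#' Select phasic genes by CSD threshold
#'
#' A gene is selected iff the CSD of its four zone means strictly exceeds
#' the threshold.  Genes whose zone means are all zero have undefined CSD
#' and are excluded (reported in the `undefined` attribute).
#'
#' @param expr expression data.frame.
#' @param csd_threshold CSD cut-off (default 0.15).
#' @return data.frame: gene_id, csd for the selected genes, ordered by
#'   decreasing CSD; attribute `undefined` holds ids of zero-mean genes.
#' @export
select_degs <- function(expr, csd_threshold = 0.15) {
  zm <- expr_zone_means(expr)
  means <- rowMeans(zm)
  undef <- rownames(zm)[means == 0]
  ok <- means > 0
  csd <- apply(zm[ok, , drop = FALSE], 1L, compute_csd)
  sel <- csd > csd_threshold
  out <- data.frame(gene_id = rownames(zm)[ok][sel], csd = csd[sel],
                    row.names = NULL, stringsAsFactors = FALSE)
  out <- out[order(-out$csd), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "undefined") <- undef
  out
}

#' Cluster phasic genes into four zone-peak phase clusters
#'
#' k-means on per-gene zone-mean vectors normalised to unit mean (so
#' clustering captures the shape of a profile, not its magnitude), with
#' multiple random starts under a fixed seed.  Clusters are relabelled
#' I-IV by the zone in which their centroid peaks (I: PZ, II: PHZ, III:
#' UHZ, IV: LHZ).  If two centroids peak in the same zone the relabelling
#' falls back to ordering centroids by their expression-weighted zone
#' index and the result carries a `relabel_fallback` attribute.
#'
#' @param zone_means numeric matrix of zone means for the genes to
#'   cluster (rownames = gene ids, columns PZ, PHZ, UHZ, LHZ).
#' @param k number of clusters (default 4).
#' @param n_init random restarts for k-means (default 25).
#' @param seed RNG seed making the clustering deterministic.
#' @return data.frame of class `deg_cluster_table`: gene_id, cluster
#'   ("I".."IV"), peak_zone; attribute `centroids` holds the k x 4
#'   centroid matrix on the normalised scale.
#' @export
cluster_phases <- function(zone_means, k = 4L, n_init = 25L, seed = 1L) {
  stopifnot(is.matrix(zone_means), ncol(zone_means) == 4L,
            nrow(zone_means) >= k)
  norm <- zone_means / rowMeans(zone_means)
  set.seed(seed)
  km <- kmeans(norm, centers = k, nstart = n_init, iter.max = 100L)
  peak <- apply(km$centers, 1L, which.max)
  fallback <- anyDuplicated(peak) > 0L
  if (fallback) {
    # expression-weighted mean zone index per centroid
    widx <- as.numeric(km$centers %*% seq_len(4L)) / rowSums(km$centers)
    ord <- order(widx)
    warning("two centroids peak in the same zone; ",
            "falling back to weighted zone-index ordering", call. = FALSE)
  } else {
    ord <- order(peak)
  }
  relabel <- integer(k)
  relabel[ord] <- seq_len(k)
  cluster <- CLUSTER_IDS[relabel[km$cluster]]
  out <- data.frame(gene_id = rownames(zone_means), cluster = cluster,
                    peak_zone = ZONES[apply(zone_means, 1L, which.max)],
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "centroids") <- km$centers[ord, , drop = FALSE]
  attr(out, "relabel_fallback") <- fallback
  class(out) <- c("deg_cluster_table", "data.frame")
  out
}

#' Run the complete expression-phasing stage
#'
#' Convenience wrapper: On/Off calls, CSD-based phasic gene selection,
#' and k-means phase clustering of the selected genes.  Reference genes
#' are excluded from clustering.
#'
#' @inheritParams call_on_off
#' @inheritParams select_degs
#' @inheritParams cluster_phases
#' @return list with `onoff`, `degs` (gene_id, csd, cluster, peak_zone)
#'   and `threshold`.
#' @export
phase_expression <- function(expr, reference_on_gene = "sox9_like",
                             reference_off_gene = "col10a1_like",
                             csd_threshold = 0.15, k = 4L, n_init = 25L,
                             seed = 1L) {
  onoff <- call_on_off(expr, reference_on_gene, reference_off_gene)
  degs <- select_degs(expr, csd_threshold)
  degs <- degs[!degs$gene_id %in% c(reference_on_gene,
                                    reference_off_gene), , drop = FALSE]
  zm <- expr_zone_means(expr)[degs$gene_id, , drop = FALSE]
  clusters <- cluster_phases(zm, k = k, n_init = n_init, seed = seed)
  degs$cluster <- clusters$cluster[match(degs$gene_id, clusters$gene_id)]
  degs$peak_zone <- clusters$peak_zone[match(degs$gene_id,
                                             clusters$gene_id)]
  list(onoff = onoff, degs = degs, threshold = onoff$threshold[1L])
}
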
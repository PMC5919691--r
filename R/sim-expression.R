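#' Simulate the zone-by-replicate expression matrix
#'
#' Every gene's replicate values are its cluster's zone mean plus
#' independent Gaussian noise, truncated at zero.  Two designated
#' threshold-reference genes are appended: `sox9_like`, On in PZ/PHZ and
#' Off in the hypertrophic zones (its HZ mean, averaged over UHZ and LHZ,
#' is 356 under the default profile), and `col10a1_like`, Off in PZ and On
#' thereafter (PZ mean 511).  These two Off-zone levels are what
#' [call_on_off()] turns into the global On/Off threshold.
#'
#' @param annotation a `gene_annotation` (provides gene ids and order).
#' @param truth_genes data.frame with columns `gene_id` and `cluster`
#'   ("I".."IV").
#' @param config a [sim_config()].
#' @return data.frame: `gene_id`, then one column per zone/replicate named
#'   `<zone>_<rep>` with zones ordered PZ, PHZ, UHZ, LHZ.
#' @export
simulate_expression <- function(annotation, truth_genes, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 5L)
  ref_profiles <- rbind(
    sox9_like    = c(1000, 900, 450, 262),  # HZ mean (450+262)/2 = 356
    col10a1_like = c(511, 900, 1200, 1300)) # PZ level 511
  ids <- c(truth_genes$gene_id, rownames(ref_profiles))
  means <- rbind(
    config$zone_mean_profiles[match(truth_genes$cluster, CLUSTER_IDS), ,
                              drop = FALSE],
    ref_profiles)
  nrep <- config$n_replicates
  cols <- as.vector(t(outer(ZONES, seq_len(nrep), paste, sep = "_")))
  vals <- matrix(NA_real_, nrow = length(ids), ncol = length(cols),
                 dimnames = list(NULL, cols))
  for (z in seq_along(ZONES)) {
    for (r in seq_len(nrep)) {
      vals[, paste0(ZONES[z], "_", r)] <-
        pmax(0, means[, z] + rnorm(length(ids), 0, config$replicate_sd))
    }
  }
  cbind(data.frame(gene_id = ids, stringsAsFactors = FALSE),
        as.data.frame(vals))
}

#' Per-gene zone means of an expression matrix
#'
#' Averages replicate columns `<zone>_<rep>` per zone.
#'
#' @param expr expression data.frame as produced by [simulate_expression()]
#'   or read from `expression.tsv`.
#' @return numeric matrix, rows = genes (rownames = gene ids), columns =
#'   zones PZ, PHZ, UHZ, LHZ.
#' @export
expr_zone_means <- function(expr) {
  stopifnot("gene_id" %in% names(expr))
  zm <- sapply(ZONES, function(z) {
    cols <- grep(paste0("^", z, "_\\d+$"), names(expr), value = TRUE)
    if (!length(cols)) stop("no replicate columns found for zone ", z,
                            call. = FALSE)
    rowMeans(as.matrix(expr[, cols, drop = FALSE]))
  })
  rownames(zm) <- expr$gene_id
  zm
}
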
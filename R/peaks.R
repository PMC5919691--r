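#' Call ChIP peaks as windowed local maxima
#'
#' A position is a summit iff its coverage is the maximum within
#' `window_bp` on both sides, with ties broken to the leftmost position
#' (the coverage must strictly exceed everything in the left window and
#' be at least everything in the right window).  This rule also enforces
#' the summit-spacing invariant: two summits of the same track are always
#' more than `window_bp` apart.  A summit is emitted iff its height
#' strictly exceeds `min_height` and its Poisson upper-tail p-value,
#' computed against the track-wide mean coverage, is below `p_max`.
#'
#' The convention of the motivating datasets is a 25 bp window for SOX9
#' ChIP-seq and 50 bp for GLI ChIP-chip.
#'
#' @param coverage per-base coverage vector (`coverage[i]` = base `i - 1`).
#' @param window_bp half-window size in bp (> 0).
#' @param min_height minimum summit height (strict; default 15).
#' @param p_max maximum Poisson background p-value (default 0.05).
#' @param tf_name optional TF label carried into the output.
#' @return data.frame of class `peak_table`: tf, summit (0-based bp),
#'   height, window_bp, p_value.
#' @export
call_peaks <- function(coverage, window_bp, min_height = 15,
                       p_max = 0.05, tf_name = NA_character_) {
  check_scalar(window_bp, "window_bp", min = 1, integer = TRUE)
  stopifnot(all(coverage >= 0))
  empty <- structure(
    data.frame(tf = character(), summit = integer(), height = numeric(),
               window_bp = integer(), p_value = numeric(),
               stringsAsFactors = FALSE),
    class = c("peak_table", "data.frame"))
  n <- length(coverage)
  if (n == 0L) return(empty)
  lambda <- mean(coverage)
  cand <- which(coverage > min_height)
  if (!length(cand)) return(empty)
  is_summit <- vapply(cand, function(i) {
    left <- coverage[max(1L, i - window_bp):max(1L, i - 1L)]
    right <- coverage[min(n, i + 1L):min(n, i + window_bp)]
    lmax <- if (i == 1L) -Inf else max(left)
    rmax <- if (i == n) -Inf else max(right)
    coverage[i] > lmax && coverage[i] >= rmax
  }, logical(1L))
  s <- cand[is_summit]
  if (!length(s)) return(empty)
  p <- ppois(coverage[s] - 1, lambda, lower.tail = FALSE)
  keep <- p < p_max
  structure(
    data.frame(tf = tf_name, summit = s[keep] - 1L,
               height = coverage[s][keep],
               window_bp = as.integer(window_bp), p_value = p[keep],
               stringsAsFactors = FALSE),
    class = c("peak_table", "data.frame"))
}

#' Assign peaks to their nearest genes as binding regions
#'
#' Each summit is assigned the gene with the nearest TSS (ties to the
#' lexicographically smaller gene id), given a signed distance to the TSS
#' (negative upstream in gene orientation), and a region class with
#' precedence promoter > intron > utr3 > intergenic.  Peaks falling
#' outside their assigned gene's intergenic bounds are dropped; the count
#' of dropped peaks is recorded in the `dropped` attribute.
#'
#' @param peaks a `peak_table`.
#' @param annotation a nonempty `gene_annotation`.
#' @return data.frame of class `binding_regions`: tf, summit, height,
#'   p_value, gene_id, tss_distance, region.
#' @export
assign_peaks_to_genes <- function(peaks, annotation) {
  stopifnot(inherits(annotation, "gene_annotation"))
  if (nrow(annotation$genes) == 0L) {
    stop("gene annotation is empty", call. = FALSE)
  }
  genes <- annotation$genes
  empty <- structure(
    data.frame(tf = character(), summit = integer(), height = numeric(),
               p_value = numeric(), gene_id = character(),
               tss_distance = integer(), region = character(),
               stringsAsFactors = FALSE),
    class = c("binding_regions", "data.frame"), dropped = 0L)
  if (!nrow(peaks)) return(empty)
  gi <- nearest_gene_index(peaks$summit, genes)
  inside <- peaks$summit >= genes$intergenic_start[gi] &
    peaks$summit < genes$intergenic_end[gi]
  dropped <- sum(!inside)
  peaks <- peaks[inside, , drop = FALSE]
  gi <- gi[inside]
  if (!nrow(peaks)) { attr(empty, "dropped") <- dropped; return(empty) }
  raw_dist <- peaks$summit - genes$tss[gi]
  signed <- ifelse(genes$strand[gi] == "+", raw_dist, -raw_dist)
  out <- data.frame(tf = peaks$tf, summit = peaks$summit,
                    height = peaks$height, p_value = peaks$p_value,
                    gene_id = genes$gene_id[gi],
                    tss_distance = as.integer(signed),
                    region = classify_region(peaks$summit, gi, annotation),
                    stringsAsFactors = FALSE)
  structure(out, class = c("binding_regions", "data.frame"),
            dropped = dropped)
}

#' Flag motif sites supported by a nearby ChIP peak
#'
#' A site is peak-supported iff the distance from its midpoint to some
#' summit of the same TF is strictly below `max_dist`.
#'
#' @param sites a `motif_sites` (or `dimer_sites`) table with `start` and
#'   `end` columns.
#' @param peaks a `peak_table` or `binding_regions` with a `summit`
#'   column; should contain peaks of the TF the sites belong to.
#' @param max_dist distance threshold in bp (strict; default 250).
#' @return `sites` with logical column `peak_supported` and integer
#'   column `peak_distance` (distance to the nearest summit, NA when no
#'   peaks) appended.
#' @export
link_sites_to_peaks <- function(sites, peaks, max_dist = 250) {
  if (!nrow(sites)) {
    sites$peak_supported <- logical(0)
    sites$peak_distance <- integer(0)
    return(sites)
  }
  mid <- (sites$start + sites$end) %/% 2L
  if (!nrow(peaks)) {
    sites$peak_supported <- FALSE
    sites$peak_distance <- NA_integer_
    return(sites)
  }
  summits <- sort(peaks$summit)
  k <- findInterval(mid, summits)
  lo <- pmax(k, 1L); hi <- pmin(k + 1L, length(summits))
  d <- pmin(abs(mid - summits[lo]), abs(mid - summits[hi]))
  sites$peak_supported <- d < max_dist
  sites$peak_distance <- as.integer(d)
  sites
}

#' Find SOX9-GLI linked binding regions (SGBRs)
#'
#' One SGBR per pair of a SOX9 binding region and a GLI binding region
#' that are assigned to the same gene and whose summits are strictly
#' closer than `max_interpeak` bp (summit-to-summit).  A gene "has an
#' SGBR" iff at least one such pair exists.
#'
#' @param sox9_regions,gli_regions `binding_regions` tables for the two
#'   factors.
#' @param max_interpeak inter-peak distance threshold in bp (strict); the
#'   motivating analyses use 250 (relaxed) and 50 (stringent).
#' @return data.frame of class `sgbr_table`: gene_id, sox9_summit,
#'   gli_summit, distance, region (the SOX9 region class).
#' @export
find_sgbr <- function(sox9_regions, gli_regions, max_interpeak = 250) {
  empty <- structure(
    data.frame(gene_id = character(), sox9_summit = integer(),
               gli_summit = integer(), distance = integer(),
               region = character(), stringsAsFactors = FALSE),
    class = c("sgbr_table", "data.frame"))
  if (!nrow(sox9_regions) || !nrow(gli_regions)) return(empty)
  m <- merge(
    sox9_regions[, c("gene_id", "summit", "region")],
    gli_regions[, c("gene_id", "summit")],
    by = "gene_id", suffixes = c("_sox9", "_gli"))
  if (!nrow(m)) return(empty)
  d <- abs(m$summit_sox9 - m$summit_gli)
  keep <- d < max_interpeak
  out <- data.frame(gene_id = m$gene_id[keep],
                    sox9_summit = m$summit_sox9[keep],
                    gli_summit = m$summit_gli[keep],
                    distance = as.integer(d[keep]),
                    region = m$region[keep], stringsAsFactors = FALSE)
  out <- out[order(out$gene_id, out$sox9_summit, out$gli_summit), ,
             drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("sgbr_table", "data.frame"))
}

#' Genes carrying at least one SGBR
#'
#' @param sgbr an `sgbr_table`.
#' @return character vector of unique gene ids.
#' @export
sgbr_genes <- function(sgbr) unique(sgbr$gene_id)

#' Export peaks as BED6 intervals
#'
#' Peaks are points (summits); for interval export each is written as
#' summit +/- its calling window, score = height.
#'
#' @param peaks a `peak_table` or `binding_regions` table (needs
#'   `summit`, `height` and, for the interval width, `window_bp`; a
#'   `window_bp` argument overrides).
#' @param chrom chromosome name.
#' @param path file path.
#' @param window_bp optional half-width override.
#' @export
write_peaks_bed <- function(peaks, chrom, path, window_bp = NULL) {
  w <- if (!is.null(window_bp)) window_bp else peaks$window_bp
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = pmax(1L, peaks$summit + 1L - w),
                              end = peaks$summit + 1L + w),
    strand = "*",
    name = paste0(ifelse(is.na(peaks$tf), "peak", peaks$tf), "_",
                  peaks$summit),
    score = peaks$height)
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}
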
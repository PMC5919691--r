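# PWM scanning with conservation filtering and nearest-TSS assignment.

# Internal: encode a DNA string as integers A=1, C=2, G=3, T=4 (NA else).
encode_dna <- function(sequence) {
  match(strsplit(toupper(sequence), "")[[1L]], c("A", "C", "G", "T"))
}

# Internal: index of the gene with the TSS nearest to each position;
# ties go to the lexicographically smaller gene id.
nearest_gene_index <- function(positions, genes) {
  ord <- order(genes$tss, genes$gene_id)
  tss <- genes$tss[ord]
  k <- findInterval(positions, tss)
  lo <- pmax(k, 1L)
  hi <- pmin(k + 1L, length(tss))
  d_lo <- abs(positions - tss[lo])
  d_hi <- abs(positions - tss[hi])
  pick_hi <- d_hi < d_lo |
    (d_hi == d_lo & genes$gene_id[ord][hi] < genes$gene_id[ord][lo])
  ord[ifelse(pick_hi, hi, lo)]
}

# Internal: region class of site midpoints relative to their assigned
# gene, precedence promoter > intron > utr3 > intergenic.
classify_region <- function(midpoints, gene_idx, annotation) {
  genes <- annotation$genes
  region <- rep("intergenic", length(midpoints))
  in_prom <- midpoints >= genes$promoter_start[gene_idx] &
    midpoints < genes$promoter_end[gene_idx]
  ints <- annotation$introns
  in_intron <- vapply(seq_along(midpoints), function(i) {
    g <- genes$gene_id[gene_idx[i]]
    rows <- ints$gene_id == g
    any(midpoints[i] >= ints$start[rows] & midpoints[i] < ints$end[rows])
  }, logical(1L))
  if (!is.null(annotation$utr3)) {
    u <- annotation$utr3
    in_utr3 <- vapply(seq_along(midpoints), function(i) {
      g <- genes$gene_id[gene_idx[i]]
      rows <- u$gene_id == g
      any(midpoints[i] >= u$start[rows] & midpoints[i] < u$end[rows])
    }, logical(1L))
    region[in_utr3] <- "utr3"
  }
  region[in_intron] <- "intron"
  region[in_prom] <- "promoter"
  region
}

#' Scan a genome for conserved PWM matches near transcription starts
#'
#' Both strands are scanned at every position; a site is emitted iff its
#' min-max similarity strictly exceeds `sim_min`, the minimum per-base
#' conservation over the site strictly exceeds `cons_min`, and the site
#' midpoint lies within `tss_window` of some TSS.  Each site is assigned
#' the gene with the nearest TSS and a genomic region class (promoter >
#' intron > utr3 > intergenic precedence).
#'
#' @param x a [pwm()] object.
#' @param sequence chromosome sequence (character scalar).
#' @param conservation per-base conservation vector (0-1000 scale),
#'   `conservation[i]` scoring base `i - 1` in 0-based coordinates;
#'   positions beyond its length score 0.
#' @param annotation a `gene_annotation` with at least one gene.
#' @param sim_min similarity threshold (strict; default 0.85).
#' @param cons_min conservation threshold (strict; default 300).
#' @param tss_window maximal distance (bp) from site midpoint to the
#'   nearest TSS (default 10000).
#' @return data.frame of class `motif_sites`: gene_id, chrom, start, end
#'   (0-based half-open), strand, similarity, conservation (site minimum),
#'   region.
#' @export
scan_conserved_sites <- function(x, sequence, conservation, annotation,
                                 sim_min = 0.85, cons_min = 300,
                                 tss_window = 10000) {
  stopifnot(inherits(x, "pwm"), inherits(annotation, "gene_annotation"))
  if (nrow(annotation$genes) == 0L) {
    stop("gene annotation is empty", call. = FALSE)
  }
  code <- encode_dna(sequence)
  L <- length(code)
  W <- x$width
  cons <- c(as.numeric(conservation),
            numeric(max(0L, L - length(conservation))))
  hit_rows <- function(scores, strand) {
    starts <- which(scores > sim_min) - 1L   # 0-based site starts
    if (!length(starts)) return(NULL)
    cmin <- vapply(starts, function(s) min(cons[(s + 1L):(s + W)]),
                   numeric(1L))
    keep <- cmin > cons_min
    starts <- starts[keep]
    if (!length(starts)) return(NULL)
    data.frame(start = starts, end = starts + W, strand = strand,
               similarity = scores[starts + 1L][keep],
               conservation = cmin[keep], stringsAsFactors = FALSE)
  }
  hits <- rbind(hit_rows(pwm_scores_all(x, code), "+"),
                hit_rows(pwm_scores_all(pwm_revcomp(x), code), "-"))
  empty <- data.frame(gene_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      strand = character(), similarity = numeric(),
                      conservation = numeric(), region = character(),
                      stringsAsFactors = FALSE)
  if (is.null(hits) || !nrow(hits)) {
    return(structure(empty, class = c("motif_sites", "data.frame")))
  }
  mid <- (hits$start + hits$end) %/% 2L
  gi <- nearest_gene_index(mid, annotation$genes)
  dist <- abs(mid - annotation$genes$tss[gi])
  keep <- dist <= tss_window
  hits <- hits[keep, , drop = FALSE]
  gi <- gi[keep]
  mid <- mid[keep]
  if (!nrow(hits)) {
    return(structure(empty, class = c("motif_sites", "data.frame")))
  }
  out <- data.frame(gene_id = annotation$genes$gene_id[gi],
                    chrom = annotation$chrom,
                    start = hits$start, end = hits$end,
                    strand = hits$strand,
                    similarity = hits$similarity,
                    conservation = hits$conservation,
                    region = classify_region(mid, gi, annotation),
                    stringsAsFactors = FALSE)
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("motif_sites", "data.frame"))
}
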
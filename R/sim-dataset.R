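#' Built-in example position weight matrices
#'
#' Small PWMs for the two motif families the pipeline revolves around: a
#' SOX9-like HMG-box monomer (consensus `AACAAT`) and a GLI-like zinc-finger
#' motif (consensus `GACCACCCA`).  Each column gives the consensus base a
#' frequency of 0.85 and 0.05 to the others, so the consensus string scores
#' exactly 1 under the min-max similarity of [pwm_similarity()].
#'
#' @return named list of [pwm()] objects.
#' @export
example_pwms <- function() {
  from_consensus <- function(name, consensus, dominant = 0.85) {
    b <- strsplit(consensus, "")[[1L]]
    m <- matrix((1 - dominant) / 3, nrow = 4L, ncol = length(b),
                dimnames = list(c("A", "C", "G", "T"), NULL))
    m[cbind(match(b, rownames(m)), seq_along(b))] <- dominant
    pwm(name, m)
  }
  list(SOX9 = from_consensus("SOX9", "AACAAT"),
       GLI = from_consensus("GLI", "GACCACCCA"))
}

#' Default motif-planting plan
#'
#' Builds the planting directives [simulate_dataset()] uses when the
#' configuration does not supply its own plan:
#' \itemize{
#'   \item every co-bound gene gets one conserved SOX9 consensus site in
#'     its promoter carrying both a SOX9 and a GLI1 coverage bump (the
#'     co-bound locus the SGBR stage must recover);
#'   \item a fraction of the remaining genes get a conserved SOX9-only
#'     site (SOX9 bump only) or a GLI1-only site (GLI consensus, GLI1
#'     bump), producing SBR-only and GBR-only genes;
#'   \item a fraction of cluster I/II genes additionally get a conserved
#'     paired half-site dimer (`AACAA` + spacer + `TTGTT`) with spacer
#'     length uniform over the configured range, without a coverage bump.
#' }
#'
#' @param annotation a `gene_annotation`.
#' @param truth_genes data.frame: gene_id, cluster, cobound.
#' @param config a [sim_config()].
#' @param sox9_only_fraction,gli_only_fraction,dimer_fraction planting
#'   probabilities described above.
#' @return list of plan entries for [plant_motifs_and_sequence()].
#' @export
default_motif_plan <- function(annotation, truth_genes, config,
                               sox9_only_fraction = 0.25,
                               gli_only_fraction = 0.10,
                               dimer_fraction = 0.30) {
  pwms <- example_pwms()
  sox_cons <- pwms$SOX9$consensus
  gli_cons <- pwms$GLI$consensus
  plan <- list()
  add <- function(...) plan[[length(plan) + 1L]] <<- list(...)
  for (i in seq_len(nrow(truth_genes))) {
    g <- truth_genes$gene_id[i]
    if (truth_genes$cobound[i]) {
      add(tf = "SOX9", type = "monomer", consensus = sox_cons,
          gene_id = g, region = "promoter", strand = "random",
          conserved = TRUE, chip_tfs = c("SOX9", "GLI1"))
    } else if (runif(1) < sox9_only_fraction) {
      add(tf = "SOX9", type = "monomer", consensus = sox_cons,
          gene_id = g, region = "promoter", strand = "random",
          conserved = TRUE, chip_tfs = "SOX9")
    } else if (runif(1) < gli_only_fraction) {
      add(tf = "GLI1", type = "monomer", consensus = gli_cons,
          gene_id = g, region = "promoter", strand = "random",
          conserved = TRUE, chip_tfs = "GLI1")
    }
    if (truth_genes$cluster[i] %in% c("I", "II") &&
        runif(1) < dimer_fraction) {
      add(tf = "SOX9", type = "dimer",
          gene_id = g, region = "promoter", strand = "+",
          spacer = sample(seq(config$spacer_min, config$spacer_max), 1L),
          conserved = TRUE, chip_tfs = character())
    }
  }
  plan
}

#' Generate the complete synthetic dataset
#'
#' Runs all five generators in order (gene models, sequence with planted
#' motifs, conservation, ChIP coverage per TF, expression) under a single
#' seed, assembling the ground truth needed to verify every downstream
#' stage.  Phase-cluster labels are drawn to match `cluster_fractions`
#' (largest-remainder rounding) and co-binding flags are Bernoulli with the
#' phasic fraction for clusters I-III and the non-phasic fraction for
#' cluster IV.
#'
#' @param config a [sim_config()].
#' @param out_dir optional directory; when given, all outputs are written
#'   via [write_dataset()] (FASTA, GFF3, BED, bedGraph, TSV, JSON).
#' @return an object of class `sim_dataset`: list with `config`,
#'   `annotation`, `sequence`, `conservation`, `chip` (named list of
#'   coverage vectors), `expression`, and `truth` (list: genes, sites,
#'   peaks).
#' @export
simulate_dataset <- function(config = sim_config(), out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  annotation <- generate_gene_models(config)

  set.seed(config$seed + 4L)
  n <- config$n_genes
  counts <- floor(config$cluster_fractions * n)
  rem <- order(config$cluster_fractions * n - counts, decreasing = TRUE)
  counts[rem[seq_len(n - sum(counts))]] <-
    counts[rem[seq_len(n - sum(counts))]] + 1L
  cluster <- if (n) sample(rep(CLUSTER_IDS, counts)) else character()
  cobound <- if (n) {
    p <- ifelse(cluster == "IV", config$cobinding_fraction_nonphasic,
                config$cobinding_fraction_phasic)
    runif(n) < p
  } else logical()
  truth_genes <- data.frame(gene_id = annotation$genes$gene_id,
                            cluster = cluster, cobound = cobound,
                            stringsAsFactors = FALSE)

  if (is.null(config$motif_plan)) {
    config$motif_plan <- default_motif_plan(annotation, truth_genes, config)
  }
  planted <- plant_motifs_and_sequence(annotation, config)
  conservation <- simulate_conservation(planted$sites, config)
  peaks <- planted_peak_centers(planted$sites, config)
  tfs <- unique(peaks$tf)
  chip <- setNames(lapply(tfs, function(tf)
    simulate_chip_coverage(peaks, tf, config)), tfs)
  expression <- simulate_expression(annotation, truth_genes, config)

  ds <- structure(list(
    config = config, annotation = annotation,
    sequence = planted$sequence, conservation = conservation,
    chip = chip, expression = expression,
    truth = list(genes = truth_genes, sites = planted$sites,
                 peaks = peaks)),
    class = "sim_dataset")
  if (!is.null(out_dir)) write_dataset(ds, out_dir)
  ds
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf(paste0("Synthetic dataset: %d genes on %s (%d bp), ",
                     "%d planted sites, %d planted summits (%s)\n"),
              nrow(x$annotation$genes), x$annotation$chrom,
              x$annotation$chrom_length, nrow(x$truth$sites),
              nrow(x$truth$peaks),
              paste(names(x$chip), collapse = ", ")))
  invisible(x)
}
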
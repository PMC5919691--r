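#' Generate non-overlapping gene models on a synthetic chromosome
#'
#' Places `n_genes` gene bodies on a single chromosome with random strand,
#' derives the strand-oriented promoter (1 kb upstream to 200 bp downstream
#' of the TSS), carves 1-3 intron intervals per gene, and records each
#' gene's intergenic bounds (from the end of its upstream neighbour's body
#' to the start of its downstream neighbour's, clipped to the chromosome).
#' Gene bodies are guaranteed pairwise non-overlapping by construction: gaps
#' between consecutive bodies are drawn by distributing the leftover length
#' proportionally to uniform weights, on top of a minimum gap.
#'
#' Coordinates are 0-based half-open throughout the package; BED/GFF3
#' conversions happen at the I/O boundary.
#'
#' @param config a [sim_config()] object.
#' @return an object of class `gene_annotation`: a list with
#'   \describe{
#'     \item{genes}{data.frame: gene_id, chrom, start, end, strand, tss,
#'       promoter_start, promoter_end, intergenic_start, intergenic_end.}
#'     \item{introns}{data.frame: gene_id, start, end.}
#'     \item{chrom, chrom_length}{chromosome name and size.}
#'   }
#' @export
generate_gene_models <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_genes
  empty <- function() {
    structure(list(
      genes = data.frame(gene_id = character(), chrom = character(),
                         start = integer(), end = integer(),
                         strand = character(), tss = integer(),
                         promoter_start = integer(), promoter_end = integer(),
                         intergenic_start = integer(),
                         intergenic_end = integer(),
                         stringsAsFactors = FALSE),
      introns = data.frame(gene_id = character(), start = integer(),
                           end = integer(), stringsAsFactors = FALSE),
      chrom = config$chrom, chrom_length = config$chrom_length),
      class = "gene_annotation")
  }
  if (n == 0L) return(empty())

  margin <- 1500L   # keeps promoters of edge genes inside the chromosome
  min_gap <- 2000L  # room for an intergenic stretch between neighbours
  lens <- sample(seq(config$gene_length_range[1L],
                     config$gene_length_range[2L]), n, replace = TRUE)
  slack <- config$chrom_length - 2L * margin - sum(lens) -
    (n - 1L) * min_gap
  if (slack < 0) {
    stop("chrom_length too small to place ", n,
         " non-overlapping genes; increase chrom_length or lower n_genes",
         call. = FALSE)
  }
  w <- runif(n + 1L)
  extra <- floor(slack * w / sum(w))
  gaps <- c(margin + extra[1L], min_gap + extra[2:n])
  starts <- cumsum(gaps) + c(0L, cumsum(lens[-n]))
  ends <- starts + lens
  strand <- sample(c("+", "-"), n, replace = TRUE)
  tss <- ifelse(strand == "+", starts, ends - 1L)
  prom <- promoter_interval(tss, strand, chrom_length = config$chrom_length)

  ig_start <- c(0L, ends[-n])
  ig_end <- c(starts[-1L], config$chrom_length)

  genes <- data.frame(
    gene_id = sprintf("g%0*d", nchar(n), seq_len(n)),
    chrom = config$chrom,
    start = as.integer(starts), end = as.integer(ends),
    strand = strand, tss = as.integer(tss),
    promoter_start = prom[, "start"], promoter_end = prom[, "end"],
    intergenic_start = as.integer(ig_start),
    intergenic_end = as.integer(ig_end),
    stringsAsFactors = FALSE)

  introns <- do.call(rbind, lapply(seq_len(n), function(i) {
    n_int <- sample(1:3, 1L)
    lo <- starts[i] + 200L
    hi <- ends[i] - 200L
    seg <- floor(seq(lo, hi, length.out = n_int + 1L))
    int_start <- int_end <- integer(n_int)
    for (j in seq_len(n_int)) {
      width <- sample(100:400, 1L)
      room <- seg[j + 1L] - seg[j] - width
      if (room <= 0) { width <- max(50L, (seg[j + 1L] - seg[j]) %/% 2L)
                       room <- seg[j + 1L] - seg[j] - width }
      off <- sample.int(max(room, 1L), 1L)
      int_start[j] <- seg[j] + off
      int_end[j] <- int_start[j] + width
    }
    data.frame(gene_id = genes$gene_id[i], start = int_start,
               end = int_end, stringsAsFactors = FALSE)
  }))

  structure(list(genes = genes, introns = introns, chrom = config$chrom,
                 chrom_length = config$chrom_length),
            class = "gene_annotation")
}

#' @export
print.gene_annotation <- function(x, ...) {
  cat(sprintf("Gene annotation: %d genes, %d introns on %s (%d bp)\n",
              nrow(x$genes), nrow(x$introns), x$chrom, x$chrom_length))
  invisible(x)
}

#' Plant motif sites into a background sequence
#'
#' Draws an i.i.d. background sequence at the configured GC fraction and
#' overwrites it with the planted sites described by the plan.  Monomer
#' entries insert the consensus string (reverse complement on the minus
#' strand); dimer entries insert the paired half-site structure
#' `AACAA + spacer + TTGTT` with background bases in the spacer.  Planting
#' positions are drawn uniformly inside the requested region of the target
#' gene (promoter, a random intron, or the gene's intergenic bounds) and
#' redrawn on collision with an already-planted site (bounded retries).
#'
#' @param annotation a `gene_annotation` from [generate_gene_models()].
#' @param config a [sim_config()]; `config$motif_plan` must be a list of
#'   entries with fields `tf`, `type` ("monomer"/"dimer"), `consensus`
#'   (monomer only), `gene_id`, `region`, `strand` ("+", "-", "random"),
#'   `spacer` (dimer only), `conserved` (logical), `chip_tfs` (character
#'   vector of TFs to receive a coverage bump at this site, possibly empty).
#' @return list with `sequence` (single character string) and `sites`
#'   (data.frame: tf, type, gene_id, start, end, strand, spacer, conserved,
#'   chip_tfs as comma-joined string), class `planted_genome`.
#' @export
plant_motifs_and_sequence <- function(annotation, config) {
  stopifnot(inherits(annotation, "gene_annotation"),
            inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  n <- config$chrom_length
  bases <- c("A", "C", "G", "T")
  p <- c((1 - config$background_gc) / 2, config$background_gc / 2,
         config$background_gc / 2, (1 - config$background_gc) / 2)
  seq_vec <- sample(bases, n, replace = TRUE, prob = p)

  plan <- config$motif_plan
  sites <- data.frame(tf = character(), type = character(),
                      gene_id = character(), start = integer(),
                      end = integer(), strand = character(),
                      spacer = integer(), conserved = logical(),
                      chip_tfs = character(), stringsAsFactors = FALSE)
  if (length(plan)) {
    occupied <- logical(n)
    genes <- annotation$genes
    rows <- vector("list", length(plan))
    for (k in seq_along(plan)) {
      e <- plan[[k]]
      gi <- match(e$gene_id, genes$gene_id)
      if (is.na(gi)) stop("motif_plan gene not in annotation: ", e$gene_id,
                          call. = FALSE)
      if (identical(e$type, "dimer")) {
        spacer <- as.integer(e$spacer)
        insert <- paste0("AACAA",
                         paste(sample(bases, spacer, replace = TRUE,
                                      prob = p), collapse = ""),
                         "TTGTT")
      } else {
        spacer <- NA_integer_
        insert <- toupper(e$consensus)
      }
      strand <- if (identical(e$strand, "random"))
        sample(c("+", "-"), 1L) else e$strand
      if (strand == "-") insert <- revcomp(insert)
      w <- nchar(insert)
      iv <- switch(e$region,
        promoter = c(genes$promoter_start[gi], genes$promoter_end[gi]),
        intron = {
          ints <- annotation$introns[
            annotation$introns$gene_id == e$gene_id, , drop = FALSE]
          j <- sample.int(nrow(ints), 1L)
          c(ints$start[j], ints$end[j])
        },
        intergenic = c(genes$intergenic_start[gi],
                       genes$intergenic_end[gi]),
        stop("unknown region class: ", e$region, call. = FALSE))
      if (iv[2L] - iv[1L] < w) {
        stop("region too small for planted site (gene ", e$gene_id, ")",
             call. = FALSE)
      }
      placed <- FALSE
      for (try in 1:50) {
        s <- iv[1L] + sample.int(iv[2L] - iv[1L] - w + 1L, 1L) - 1L
        idx <- seq.int(s + 1L, s + w)   # 1-based into seq_vec
        if (!any(occupied[idx])) {
          occupied[idx] <- TRUE
          seq_vec[idx] <- strsplit(insert, "")[[1L]]
          rows[[k]] <- data.frame(
            tf = e$tf, type = if (is.na(spacer)) "monomer" else "dimer",
            gene_id = e$gene_id, start = s, end = s + w,
            strand = strand, spacer = spacer,
            conserved = isTRUE(e$conserved),
            chip_tfs = paste(e$chip_tfs, collapse = ","),
            stringsAsFactors = FALSE)
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        stop("could not place site for gene ", e$gene_id,
             " after 50 retries (region saturated)", call. = FALSE)
      }
    }
    sites <- do.call(rbind, rows)
  }
  structure(list(sequence = paste(seq_vec, collapse = ""), sites = sites),
            class = "planted_genome")
}
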
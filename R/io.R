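# File formats: FASTA through Biostrings, GFF3/BED/bedGraph through
# rtracklayer, TSV through base R, ground truth through jsonlite.
# Internal coordinates are 0-based half-open; conversion to the 1-based
# closed convention of GRanges happens only here.

annotation_to_granges <- function(annotation) {
  genes <- annotation$genes
  gr_genes <- GenomicRanges::GRanges(
    seqnames = annotation$chrom,
    ranges = IRanges::IRanges(start = genes$start + 1L, end = genes$end),
    strand = genes$strand,
    type = "gene", ID = genes$gene_id,
    Parent = methods::as(rep(list(character(0)), nrow(genes)),
                         "CharacterList"))
  ints <- annotation$introns
  gr_introns <- GenomicRanges::GRanges(
    seqnames = annotation$chrom,
    ranges = IRanges::IRanges(start = ints$start + 1L, end = ints$end),
    strand = genes$strand[match(ints$gene_id, genes$gene_id)],
    type = "intron",
    ID = paste0(ints$gene_id, ".intron", seq_len(nrow(ints))),
    Parent = methods::as(as.list(ints$gene_id), "CharacterList"))
  c(gr_genes, gr_introns)
}

#' Write / read the synthetic genome FASTA
#'
#' @param sequence single chromosome sequence (character scalar).
#' @param chrom chromosome name.
#' @param path file path.
#' @return `read_genome_fasta` returns a named character vector of
#'   sequences.
#' @export
write_genome_fasta <- function(sequence, chrom, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(setNames(sequence, chrom)), path)
  invisible(path)
}

#' @rdname write_genome_fasta
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' Write / read gene models as GFF3
#'
#' Genes are `gene` features (attribute `ID`), introns `intron` features
#' with a `Parent` link.  Promoters and intergenic bounds are derived
#' quantities and are recomputed on read.
#'
#' @param annotation a `gene_annotation`.
#' @param path file path.
#' @param chrom_length chromosome length (bp), needed to rebuild the
#'   edge genes' intergenic bounds.
#' @return `read_annotation_gff3` returns a `gene_annotation`.
#' @export
write_annotation_gff3 <- function(annotation, path) {
  rtracklayer::export(annotation_to_granges(annotation), path,
                      format = "gff3")
  invisible(path)
}

#' @rdname write_annotation_gff3
#' @export
read_annotation_gff3 <- function(path, chrom_length) {
  gr <- rtracklayer::import(path, format = "gff3")
  is_gene <- gr$type == "gene"
  g <- gr[is_gene]
  o <- order(GenomicRanges::start(g))
  g <- g[o]
  start <- GenomicRanges::start(g) - 1L
  end <- GenomicRanges::end(g)
  strand <- as.character(GenomicRanges::strand(g))
  tss <- ifelse(strand == "+", start, end - 1L)
  prom <- promoter_interval(tss, strand, chrom_length = chrom_length)
  n <- length(g)
  genes <- data.frame(
    gene_id = g$ID,
    chrom = as.character(GenomicRanges::seqnames(g)),
    start = start, end = end, strand = strand, tss = as.integer(tss),
    promoter_start = prom[, "start"], promoter_end = prom[, "end"],
    intergenic_start = as.integer(c(0L, end[-n])),
    intergenic_end = as.integer(c(start[-1L], chrom_length)),
    stringsAsFactors = FALSE)
  iv <- gr[gr$type == "intron"]
  introns <- data.frame(
    gene_id = vapply(iv$Parent, `[`, character(1L), 1L),
    start = GenomicRanges::start(iv) - 1L,
    end = GenomicRanges::end(iv),
    stringsAsFactors = FALSE)
  structure(list(genes = genes, introns = introns,
                 chrom = genes$chrom[1L], chrom_length = chrom_length),
            class = "gene_annotation")
}

#' Write gene bodies as BED6
#'
#' @param annotation a `gene_annotation`.
#' @param path file path.
#' @export
write_genes_bed <- function(annotation, path) {
  genes <- annotation$genes
  gr <- GenomicRanges::GRanges(
    seqnames = annotation$chrom,
    ranges = IRanges::IRanges(start = genes$start + 1L, end = genes$end),
    strand = genes$strand, name = genes$gene_id, score = 0L)
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Write / read a per-base track as bedGraph
#'
#' Runs of equal value are merged into single intervals on write; reading
#' expands the intervals back to a per-base vector.
#'
#' @param values per-base numeric vector (position 1 = chromosome base 0).
#' @param chrom chromosome name.
#' @param path file path.
#' @param chrom_length expected length of the reconstructed vector.
#' @return `read_bedgraph` returns the per-base numeric vector.
#' @export
write_bedgraph <- function(values, chrom, path) {
  r <- rle(values)
  end <- cumsum(r$lengths)
  start <- end - r$lengths  # 0-based half-open, bedGraph's convention
  df <- data.frame(chrom = chrom, start = start, end = end,
                   score = r$values)
  # bedGraph is plain 4-column 0-based text; write directly
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_bedgraph
#' @export
read_bedgraph <- function(path, chrom_length) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  out <- numeric(chrom_length)
  start <- GenomicRanges::start(gr)      # 1-based inclusive
  end <- GenomicRanges::end(gr)
  for (i in seq_along(gr)) out[start[i]:end[i]] <- gr$score[i]
  out
}

#' Write / read the expression matrix TSV
#'
#' Columns: `gene_id`, then `<zone>_<rep>` for zones PZ, PHZ, UHZ, LHZ.
#'
#' @param expr expression data.frame.
#' @param path file path.
#' @export
write_expression_tsv <- function(expr, path) {
  write.table(expr, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(path) {
  read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Write every output of a synthetic dataset to a directory
#'
#' Emits `genome.fa`, `genes.gff3`, `genes.bed`, `conservation.bedgraph`,
#' `chip_<tf>.bedgraph` per TF, `expression.tsv` and `truth.json`.
#'
#' @param ds a `sim_dataset` from [simulate_dataset()].
#' @param dir output directory (created if absent).
#' @return invisibly, the named vector of written paths.
#' @export
write_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "sim_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    genome = file.path(dir, "genome.fa"),
    gff3 = file.path(dir, "genes.gff3"),
    bed = file.path(dir, "genes.bed"),
    conservation = file.path(dir, "conservation.bedgraph"),
    expression = file.path(dir, "expression.tsv"),
    truth = file.path(dir, "truth.json"))
  write_genome_fasta(ds$sequence, ds$annotation$chrom, paths["genome"])
  write_annotation_gff3(ds$annotation, paths["gff3"])
  write_genes_bed(ds$annotation, paths["bed"])
  write_bedgraph(ds$conservation, ds$annotation$chrom,
                 paths["conservation"])
  for (tf in names(ds$chip)) {
    p <- file.path(dir, sprintf("chip_%s.bedgraph", tolower(tf)))
    write_bedgraph(ds$chip[[tf]], ds$annotation$chrom, p)
    paths[paste0("chip_", tolower(tf))] <- p
  }
  write_expression_tsv(ds$expression, paths["expression"])
  jsonlite::write_json(ds$truth, paths["truth"], dataframe = "columns",
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
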
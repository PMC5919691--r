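#' Shuffle sequences preserving mononucleotide composition
#'
#' Permutes the bases of each sequence independently; the per-sequence
#' base multiset is preserved exactly.  Deterministic per seed.  Used to
#' build the background set for discriminative word enrichment.
#'
#' @param sequences character vector of DNA sequences.
#' @param seed RNG seed.
#' @return character vector of shuffled sequences.
#' @export
shuffle_background <- function(sequences, seed = 1L) {
  set.seed(seed)
  vapply(sequences, function(s) {
    paste(sample(strsplit(s, "")[[1L]]), collapse = "")
  }, character(1L), USE.NAMES = FALSE)
}

# Internal: total (overlapping) k-mer occurrence counts on both strands.
# Returns list(counts = named integer vector, n_windows = total windows).
count_words <- function(sequences, width) {
  all_words <- unlist(lapply(sequences, function(s) {
    out <- character(0)
    for (str in c(s, revcomp(s))) {
      n <- nchar(str)
      if (n >= width) {
        out <- c(out, substring(str, 1:(n - width + 1L), width:n))
      }
    }
    out
  }))
  all_words <- all_words[!grepl("[^ACGT]", all_words)]
  list(counts = table(all_words), n_windows = length(all_words))
}

#' Discriminative word enrichment by foreground/background ratio
#'
#' Counts all overlapping occurrences of every exact `width`-mer on both
#' strands in foreground (e.g. cluster promoters) and background (e.g.
#' shuffled promoters), and ranks words by the length-normalised,
#' pseudocount-adjusted ratio
#' `((fg + 1) / (bg + 1)) * (bg_windows / fg_windows)`.
#' Ties rank by descending foreground count, then lexicographically.
#'
#' @param fg_sequences,bg_sequences character vectors of sequences; both
#'   nonempty, each at least `width` long.
#' @param width word length.
#' @param min_ratio minimum ratio to report (default 2).
#' @param top_n maximum number of words to report (default 50).
#' @return data.frame of class `word_enrichment`: word, fg_count,
#'   bg_count, fg_bg_ratio, rank.
#' @export
word_enrichment <- function(fg_sequences, bg_sequences, width,
                            min_ratio = 2, top_n = 50L) {
  stopifnot(length(fg_sequences) > 0, length(bg_sequences) > 0,
            width >= 1L,
            min(nchar(c(fg_sequences, bg_sequences))) >= width)
  fg <- count_words(fg_sequences, width)
  bg <- count_words(bg_sequences, width)
  words <- sort(unique(c(names(fg$counts), names(bg$counts))))
  fgc <- as.integer(fg$counts[words]); fgc[is.na(fgc)] <- 0L
  bgc <- as.integer(bg$counts[words]); bgc[is.na(bgc)] <- 0L
  ratio <- ((fgc + 1) / (bgc + 1)) * (bg$n_windows / fg$n_windows)
  out <- data.frame(word = words, fg_count = fgc, bg_count = bgc,
                    fg_bg_ratio = ratio, stringsAsFactors = FALSE)
  out <- out[order(-out$fg_bg_ratio, -out$fg_count, out$word), ,
             drop = FALSE]
  out <- out[out$fg_bg_ratio >= min_ratio, , drop = FALSE]
  out <- head(out, top_n)
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  structure(out, class = c("word_enrichment", "data.frame"))
}

#' Extract promoter sequences for a set of genes
#'
#' Convenience accessor used by the word-enrichment stage: returns the
#' promoter interval sequence (strand-oriented 1 kb upstream to 200 bp
#' downstream of the TSS, as stored in the annotation) for each requested
#' gene, reverse-complemented for minus-strand genes so all promoters
#' read 5' to 3'.
#'
#' @param sequence chromosome sequence.
#' @param annotation a `gene_annotation`.
#' @param gene_ids genes to extract; default all.
#' @return named character vector of promoter sequences.
#' @export
promoter_sequences <- function(sequence, annotation,
                               gene_ids = annotation$genes$gene_id) {
  genes <- annotation$genes
  idx <- match(gene_ids, genes$gene_id)
  if (anyNA(idx)) stop("unknown gene ids", call. = FALSE)
  out <- substring(sequence, genes$promoter_start[idx] + 1L,
                   genes$promoter_end[idx])
  minus <- genes$strand[idx] == "-"
  out[minus] <- revcomp(out[minus])
  setNames(out, gene_ids)
}
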
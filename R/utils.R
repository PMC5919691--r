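#' Reverse complement of a DNA string
#'
#' Thin character-vector wrapper over [Biostrings::reverseComplement()] used
#' throughout the scanning code, which works on plain R strings.
#'
#' @param x character vector of DNA sequences (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @export
#' @examples
#' revcomp("AACAA")  # "TTGTT"
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Report a count pair as a rounded percentage
#'
#' The pipeline's bookkeeping helper: given a numerator and denominator count
#' it returns the percentage rounded to the nearest integer, the form in
#' which headline fractions (e.g. commonly expressed genes, SGBR-bearing
#' target genes) are reported.
#'
#' @param numerator,denominator nonnegative counts; `denominator > 0`.
#' @return numeric percentage rounded to 0 decimal places.
#' @export
#' @examples
#' percent_of(4792, 4886)  # 98
#' percent_of(721, 1426)   # 51
percent_of <- function(numerator, denominator) {
  stopifnot(length(numerator) == length(denominator),
            all(numerator >= 0), all(denominator > 0))
  round(100 * numerator / denominator)
}

# Internal: sample a random DNA string of length n at a given GC fraction.
random_dna <- function(n, gc = 0.42) {
  if (n <= 0) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# Internal: strand-aware promoter interval [TSS-1000, TSS+200] (0-based
# half-open, oriented by strand), clipped to [0, chrom_length).
promoter_interval <- function(tss, strand, upstream = 1000L, downstream = 200L,
                              chrom_length = Inf) {
  start <- ifelse(strand == "+", tss - upstream, tss - downstream + 1L)
  end <- ifelse(strand == "+", tss + downstream + 1L, tss + upstream + 1L)
  cbind(start = pmax(0L, as.integer(start)),
        end = pmin(as.integer(end), as.integer(chrom_length)))
}

# Internal: stop unless x is a single finite number (optionally integerish).
check_scalar <- function(x, name, min = -Inf, integer = FALSE) {
  if (length(x) != 1L || !is.finite(x) || x < min ||
      (integer && x != round(x))) {
    stop(sprintf("'%s' must be a single finite %s >= %s", name,
                 if (integer) "integer" else "number", format(min)),
         call. = FALSE)
  }
  invisible(x)
}
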
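#' Exact two-tailed Fisher p-value for a 2x2 table
#'
#' Enumerates the hypergeometric distribution over all tables with the
#' observed margins.  The default two-tailed rule is the probability-mass
#' rule: the p-value sums the probabilities of all tables at most as
#' probable as the observed one (with a relative tolerance of 1e-7 on the
#' comparison).  The doubling rule (twice the smaller tail, capped at 1)
#' is available as an alternative.
#'
#' @param a,b,c,d nonnegative integer cell counts; rows are the two gene
#'   groups, columns with/without the property.
#' @param method two-tailed rule: `"mass"` (default) or `"doubling"`.
#' @return p-value in (0, 1].
#' @export
fisher_exact_p <- function(a, b, c, d, method = c("mass", "doubling")) {
  method <- match.arg(method)
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("cell counts must be nonnegative integers", call. = FALSE)
  }
  m <- a + b; n <- c + d; k <- a + c
  x <- seq(max(0L, k - n), min(k, m))
  probs <- dhyper(x, m, n, k)
  obs <- dhyper(a, m, n, k)
  if (method == "mass") {
    sum(probs[probs <= obs * (1 + 1e-7)])
  } else {
    lower <- sum(probs[x <= a])
    upper <- sum(probs[x >= a])
    min(1, 2 * min(lower, upper))
  }
}

#' Fisher test and relative-representation odds ratio for a 2x2 table
#'
#' Computes the two-tailed Fisher exact p-value together with two odds
#' ratios: the relative-representation ratio
#' `relative_risk = (a / c) / ((a + b) / (c + d))` (the published form:
#' phasic-group SGBR count over reference-group SGBR count, divided by
#' the corresponding group-size ratio) and the canonical cross-product
#' ratio `ad / bc`.  The relative-representation ratio equals 1 exactly
#' when the two groups have equal SGBR proportions, 0 when `a = 0`, and
#' is flagged undefined when `c = 0` (infinite when additionally
#' `a > 0`).
#'
#' @param a phasic-group genes with the property (e.g. an SGBR).
#' @param b phasic-group genes without.
#' @param c reference-group genes with.
#' @param d reference-group genes without.
#' @param method two-tailed rule passed to [fisher_exact_p()].
#' @param label optional description of the grouping.
#' @return object of class `enrichment_result`: list with the four
#'   counts, `relative_risk`, `odds_ratio`, `fisher_p`,
#'   `or_undefined`, `label`.
#' @export
#' @examples
#' r <- fisher_or(8, 2, 2, 8)
#' r$relative_risk  # 4
#' r$fisher_p          # 0.02301
fisher_or <- function(a, b, c, d, method = c("mass", "doubling"),
                      label = NA_character_) {
  counts <- base::c(a, b, c, d)
  if (any(counts < 0)) stop("cell counts must be nonnegative",
                            call. = FALSE)
  undefined <- c == 0
  rr <- if (undefined) {
    if (a == 0) NaN else Inf
  } else {
    (a / c) / ((a + b) / (c + d))
  }
  canon <- if (b * c == 0) {
    if (a * d == 0) NaN else Inf
  } else {
    (a * d) / (b * c)
  }
  structure(list(a = a, b = b, c = c, d = d,
                 relative_risk = rr,
                 odds_ratio = canon,
                 fisher_p = fisher_exact_p(a, b, c, d, method),
                 or_undefined = undefined, label = label),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("2x2 enrichment%s\n",
              if (is.na(x$label)) "" else paste0(" (", x$label, ")")))
  cat(sprintf("  counts: a=%d b=%d c=%d d=%d\n", x$a, x$b, x$c, x$d))
  cat(sprintf("  relative-representation odds ratio: %s%s\n",
              format(x$relative_risk),
              if (x$or_undefined) " (undefined: c = 0)" else ""))
  cat(sprintf("  canonical odds ratio: %s\n",
              format(x$odds_ratio)))
  cat(sprintf("  two-tailed Fisher p: %.4g\n", x$fisher_p))
  invisible(x)
}
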
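#' Pearson chi-square goodness-of-fit test for an allele count pair
#'
#' Tests whether the observed (maternal, paternal) read counts of a gene are
#' consistent with an expected maternal read fraction. The expectation encodes
#' the parental genome dosage of the tissue: 1:1 (fraction 0.5) in the embryo
#' and 2:1 (fraction 2/3) in the triploid endosperm, which carries two
#' maternal genome copies and one paternal copy.
#'
#' The statistic is the one-degree-of-freedom Pearson goodness-of-fit
#' statistic on the two-cell observed vector against expected counts
#' `total * f` and `total * (1 - f)`; the p-value is the upper tail of
#' chi-square(1). No continuity correction is applied by default.
#'
#' All arguments are vectorized and recycled to a common length.
#'
#' @param maternal_count,paternal_count Non-negative read counts; each pair
#'   must total at least one read.
#' @param expected_maternal_fraction Expected maternal fraction, strictly
#'   inside (0, 1).
#' @param continuity_correction Apply the Yates correction (subtract 0.5 from
#'   each absolute cell deviation, floored at zero). Default `FALSE`.
#' @return A list with numeric vectors `statistic` and `p_value`.
#' @examples
#' chi_square_gof(20, 20, 0.5)      # statistic 0, p = 1
#' chi_square_gof(30, 10, 2 / 3)    # statistic 1.25
#' @export
chi_square_gof <- function(maternal_count, paternal_count,
                           expected_maternal_fraction,
                           continuity_correction = FALSE) {
  n <- max(length(maternal_count), length(paternal_count),
           length(expected_maternal_fraction))
  m <- rep_len(as.numeric(maternal_count), n)
  p <- rep_len(as.numeric(paternal_count), n)
  f <- rep_len(as.numeric(expected_maternal_fraction), n)
  if (any(!is.finite(m)) || any(!is.finite(p)) || any(m < 0) || any(p < 0)) {
    stop("Counts must be finite and non-negative", call. = FALSE)
  }
  total <- m + p
  if (any(total < 1)) {
    stop("chi_square_gof() requires at least one read per gene (zero totals found)",
         call. = FALSE)
  }
  if (any(f <= 0) || any(f >= 1)) {
    stop("expected_maternal_fraction must lie strictly inside (0, 1)",
         call. = FALSE)
  }
  exp_m <- total * f
  exp_p <- total * (1 - f)
  # Two cells share a single absolute deviation |m - E[m]| = |p - E[p]|.
  dev <- abs(m - exp_m)
  if (continuity_correction) dev <- pmax(dev - 0.5, 0)
  statistic <- dev^2 / exp_m + dev^2 / exp_p
  list(statistic = statistic,
       p_value = pchisq(statistic, df = 1, lower.tail = FALSE))
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Standard step-up BH adjustment of a p-value vector. Thin validated wrapper
#' around [stats::p.adjust()] so every stage of the pipeline corrects p-values
#' the same way.
#'
#' @param p Numeric vector of p-values in \[0, 1\]; must be non-empty.
#' @param ids Optional identifiers aligned to `p`; must be unique. Used only
#'   for naming the result.
#' @return Numeric vector of q-values, named by `ids` when supplied.
#' @export
bh_adjust <- function(p, ids = NULL) {
  if (length(p) == 0) stop("bh_adjust() requires a non-empty p-value vector",
                           call. = FALSE)
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1] with no missing values", call. = FALSE)
  }
  if (!is.null(ids)) {
    if (length(ids) != length(p)) stop("ids must align with p", call. = FALSE)
    if (anyDuplicated(ids)) stop("ids must be unique", call. = FALSE)
  }
  q <- p.adjust(p, method = "BH")
  if (!is.null(ids)) names(q) <- ids
  q
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' Computes the two-sample KS statistic `D = sup |ECDF_a - ECDF_b|` and its
#' asymptotic two-sided p-value, as used to compare percent-spliced-in (PSI)
#' distributions between reciprocal crosses. Exact small-sample p-values are
#' deliberately not used: the comparison operates on thousands of PSI values,
#' where the asymptotic distribution is appropriate and tie-tolerant.
#'
#' @param a,b Non-empty numeric vectors.
#' @return A list with `D` (in \[0, 1\]) and `p_value`.
#' @export
ks_two_sample <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) {
    stop("ks_two_sample() requires two non-empty samples", call. = FALSE)
  }
  if (any(!is.finite(a)) || any(!is.finite(b))) {
    stop("Samples must be finite numeric vectors", call. = FALSE)
  }
  res <- suppressWarnings(ks.test(a, b, alternative = "two.sided", exact = FALSE))
  list(D = unname(res$statistic), p_value = res$p.value)
}
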
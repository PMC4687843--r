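#' Transform a p-value to a signed z-score (Wald statistic)
#'
#' Uses the one-tailed inverse-normal transform: the magnitude is the
#' upper-tail standard-normal quantile of `p`, and the sign is taken from
#' `direction` (positive when the direction is unknown). This is the
#' convention under which published per-SNP Wald statistics are recovered
#' from their printed p-values.
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @param direction Optional vector of effect directions (-1, +1, or `NA`
#'   for unknown). Recycled against `p`.
#' @return Numeric vector of signed z-scores.
#' @examples
#' p_to_z(7.78e-8, -1)   # about -5.25
#' p_to_z(0.5)           # exactly 0
#' @export
p_to_z <- function(p, direction = NULL) {
  if (any(is.na(p)) || any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1]", call. = FALSE)
  z <- stats::qnorm(p, lower.tail = FALSE)
  if (!is.null(direction)) {
    direction <- rep_len(direction, length(p))
    sgn <- ifelse(!is.na(direction) & direction < 0, -1, 1)
    z <- sgn * z
  }
  z
}

#' Inverse of [p_to_z()]
#'
#' @param z Signed z-scores.
#' @param direction Directions used in the forward transform (default +1).
#' @return p-values in (0, 1].
#' @export
z_to_p <- function(z, direction = 1) {
  direction <- rep_len(direction, length(z))
  sgn <- ifelse(!is.na(direction) & direction < 0, -1, 1)
  stats::pnorm(sgn * z, lower.tail = FALSE)
}

#' Estimate the genomic-control inflation factor from intergenic SNPs
#'
#' Computes the genomic inflation factor lambda_GC as the median squared
#' z-score over the masked (intergenic) SNPs divided by the median of a
#' chi-square distribution with one degree of freedom. Intergenic SNPs are
#' used because they are depleted of true associations across complex
#' traits, so their median chi-square reflects stratification-driven
#' inflation rather than polygenic signal.
#'
#' @param z Numeric vector of z-scores for one trait.
#' @param intergenic_mask Logical vector selecting the intergenic SNPs. If
#'   `NULL`, all SNPs are used, with a prominent warning.
#' @param min_intergenic Warning threshold on the number of masked SNPs.
#' @return Object of class `"gc_estimate"`: list with `lambda_gc`,
#'   `n_intergenic`, and `chi2_median_expected` (the chi-square(1) median,
#'   computed from the inverse chi-square CDF).
#' @export
estimate_lambda_gc <- function(z, intergenic_mask = NULL,
                               min_intergenic = 1000L) {
  if (is.null(intergenic_mask)) {
    warning("no intergenic mask supplied: estimating lambda_GC from ALL SNPs; ",
            "polygenic signal may inflate the estimate", call. = FALSE)
    intergenic_mask <- rep(TRUE, length(z))
  }
  stopifnot(length(intergenic_mask) == length(z))
  zm <- z[intergenic_mask & !is.na(z)]
  if (length(zm) == 0L)
    stop("intergenic mask selects no SNPs", call. = FALSE)
  if (length(zm) < min_intergenic)
    warning("only ", length(zm), " intergenic SNPs available for lambda_GC ",
            "(recommended >= ", min_intergenic, ")", call. = FALSE)
  chi2_median_expected <- stats::qchisq(0.5, df = 1)
  med <- stats::median(zm^2)
  if (med == 0)
    stop("degenerate z-scores: median z^2 is 0, lambda_GC undefined",
         call. = FALSE)
  lambda <- med / chi2_median_expected
  if (lambda < 1)
    warning("lambda_GC = ", signif(lambda, 4),
            " < 1 (deflation); applied as-is without clipping", call. = FALSE)
  structure(list(lambda_gc = lambda, n_intergenic = length(zm),
                 chi2_median_expected = chi2_median_expected),
            class = "gc_estimate")
}

#' @export
print.gc_estimate <- function(x, ...) {
  cat(sprintf("lambda_GC = %.4f (estimated from %d intergenic SNPs)\n",
              x$lambda_gc, x$n_intergenic))
  invisible(x)
}

#' Apply a genomic-control correction to p-values
#'
#' Each p-value is converted to its 1-df chi-square deviate, the deviate is
#' divided by `lambda_gc`, and the corrected p-value is the upper-tail
#' chi-square(1) probability of the rescaled deviate. Deflation factors
#' (lambda < 1) are applied as-is. Corrected p-values are floored at
#' `p_floor`.
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @param gc A `gc_estimate` (or a bare positive number).
#' @param p_floor Floor applied to the corrected p-values.
#' @return Corrected p-value vector.
#' @export
apply_gc <- function(p, gc, p_floor = P_FLOOR) {
  lambda <- if (inherits(gc, "gc_estimate")) gc$lambda_gc else as.numeric(gc)
  if (!is.finite(lambda) || lambda <= 0)
    stop("lambda_GC must be a positive finite number", call. = FALSE)
  if (any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1]", call. = FALSE)
  chi2 <- stats::qchisq(p, df = 1, lower.tail = FALSE)
  out <- stats::pchisq(chi2 / lambda, df = 1, lower.tail = FALSE)
  pmin(1, pmax(p_floor, out))
}

#' Genomic-control correction of a whole summary-statistics table
#'
#' Convenience wrapper: estimates lambda_GC from the table's intergenic SNPs
#' (falling back to all SNPs, with a warning, when no category column is
#' informative) and returns the table with corrected p-values. The z-score
#' magnitudes are recovered from the p-values through the 1-df chi-square
#' deviate (the two-sided relation `z^2 = qchisq(p, 1, lower.tail = FALSE)`),
#' which reproduces the squared association z-score exactly and matches the
#' deviate rescaled by [apply_gc()].
#'
#' @param sumstats A `sumstats` table.
#' @param min_intergenic Passed to [estimate_lambda_gc()].
#' @return The corrected table, with the `gc_estimate` in attribute `"gc"`.
#' @export
gc_correct_sumstats <- function(sumstats, min_intergenic = 1000L) {
  z <- sqrt(stats::qchisq(sumstats$p, df = 1, lower.tail = FALSE))
  mask <- sumstats$category == "intergenic"
  if (!any(mask)) mask <- NULL
  gc <- estimate_lambda_gc(z, mask, min_intergenic = min_intergenic)
  sumstats$p <- apply_gc(sumstats$p, gc)
  attr(sumstats, "gc") <- gc
  sumstats
}
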
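#' Stratify panel SNPs by conditioning-trait significance
#'
#' Builds the nested SNP strata used by conditional Q-Q plots: for each
#' threshold t in the ladder, the stratum is the set of SNPs whose
#' conditioning-trait p-value satisfies -log10(p2) >= t. Threshold 0
#' therefore contains every SNP, and the strata are nested.
#'
#' @param panel An `aligned_panel`.
#' @param trait Name (or index) of the conditioning trait.
#' @param thresholds Nondecreasing ladder of -log10(p2) cut-offs.
#' @param min_stratum Warn when a stratum is smaller than this.
#' @return Named list of integer index vectors, one per threshold.
#' @export
qq_stratify <- function(panel, trait, thresholds = c(0, 1, 2, 3),
                        min_stratum = 100L) {
  if (is.unsorted(thresholds))
    stop("thresholds must be nondecreasing", call. = FALSE)
  p2 <- panel$p_cond[[trait]]
  if (is.null(p2)) stop("unknown conditioning trait: ", trait, call. = FALSE)
  neglog <- -log10(p2)
  sets <- lapply(thresholds, function(t) which(neglog >= t))
  names(sets) <- paste0("p2_geq_", thresholds)
  small <- vapply(sets, length, 0L) < min_stratum
  if (any(small))
    warning("stratum size below ", min_stratum, " for threshold(s) ",
            paste(thresholds[small], collapse = ", "), call. = FALSE)
  attr(sets, "thresholds") <- thresholds
  sets
}

#' Empirical Q-Q curve for one stratum
#'
#' Pairs the i-th order statistic p(i) of the stratum with the empirical
#' quantile q = i/n (right-continuous ECDF convention), and returns the
#' curve on the -log10 scale: x = -log10(q), y = -log10(p). Points with
#' nominal -log10(p) at or above `focus_max_logp` (genome-wide significant
#' SNPs) are excluded from display only, to focus on sub-threshold
#' polygenic signal.
#'
#' @param p p-values of one stratum.
#' @param focus_max_logp Display ceiling on nominal -log10(p); default 7.3
#'   (p = 5e-8).
#' @param stratum_threshold Optional -log10(p2) threshold label.
#' @return Object of class `"qq_curve"`: list with `points` (data.frame of
#'   `neglog_q`, `neglog_p`, ordered by ascending p), `n_snps`, and
#'   `stratum_threshold`. Empty input yields an empty, flagged curve.
#' @export
qq_curve <- function(p, focus_max_logp = 7.3, stratum_threshold = NA_real_) {
  n <- length(p)
  if (n == 0L) {
    warning("empty stratum: returning empty Q-Q curve", call. = FALSE)
    return(structure(list(points = data.frame(neglog_q = numeric(0),
                                              neglog_p = numeric(0)),
                          n_snps = 0L, stratum_threshold = stratum_threshold,
                          empty = TRUE),
                     class = "qq_curve"))
  }
  ps <- sort(p)
  q <- seq_len(n) / n
  pts <- data.frame(neglog_q = -log10(q), neglog_p = -log10(ps))
  pts <- pts[pts$neglog_p < focus_max_logp, , drop = FALSE]
  rownames(pts) <- NULL
  structure(list(points = pts, n_snps = n,
                 stratum_threshold = stratum_threshold, empty = FALSE),
            class = "qq_curve")
}

#' Conditional Q-Q curves for pleiotropic enrichment
#'
#' Computes one Q-Q curve of primary-trait p-values per conditioning-trait
#' stratum. Successive leftward shifts of the curves with increasing
#' stratum stringency indicate enrichment of primary-trait signal among
#' SNPs associated with the conditioning trait (pleiotropy).
#'
#' @inheritParams qq_stratify
#' @param focus_max_logp Display ceiling on nominal -log10(p).
#' @return Object of class `"conditional_qq"`: list of `qq_curve`s, one per
#'   threshold, plus the trait name and ladder.
#' @export
conditional_qq <- function(panel, trait, thresholds = c(0, 1, 2, 3),
                           focus_max_logp = 7.3) {
  strata <- qq_stratify(panel, trait, thresholds)
  curves <- mapply(function(idx, t) {
    qq_curve(panel$p_primary[idx], focus_max_logp = focus_max_logp,
             stratum_threshold = t)
  }, strata, thresholds, SIMPLIFY = FALSE)
  structure(list(curves = curves, trait = trait, thresholds = thresholds,
                 focus_max_logp = focus_max_logp),
            class = "conditional_qq")
}

#' @export
print.conditional_qq <- function(x, ...) {
  cat("Conditional Q-Q curves | conditioning trait:", x$trait, "\n")
  for (cu in x$curves)
    cat(sprintf("  -log10(p2) >= %g : %d SNPs\n",
                cu$stratum_threshold, cu$n_snps))
  invisible(x)
}

#' Plot conditional Q-Q curves
#'
#' One curve per stratum; the dotted diagonal is the global null
#' (uniform p-values).
#'
#' @param x A `conditional_qq` object.
#' @param col Colours, one per stratum.
#' @param ... Further arguments passed to [graphics::plot()].
#' @export
plot.conditional_qq <- function(x, col = NULL, ...) {
  curves <- Filter(function(cu) nrow(cu$points) > 0, x$curves)
  if (length(curves) == 0L) stop("no non-empty curves to plot", call. = FALSE)
  if (is.null(col)) col <- grDevices::hcl.colors(length(x$curves), "Dark 2")
  xmax <- max(vapply(curves, function(cu) max(cu$points$neglog_q), 0))
  ymax <- max(vapply(curves, function(cu) max(cu$points$neglog_p), 0))
  graphics::plot(NA, xlim = c(0, xmax * 1.04), ylim = c(0, ymax * 1.04),
                 xlab = expression(-log[10](q)),
                 ylab = expression(-log[10](p)),
                 main = paste0("Conditional Q-Q | ", x$trait), ...)
  graphics::abline(0, 1, lty = 3)
  for (i in seq_along(x$curves)) {
    cu <- x$curves[[i]]
    if (nrow(cu$points) == 0) next
    graphics::lines(cu$points$neglog_q, cu$points$neglog_p, col = col[i],
                    lwd = 2)
  }
  graphics::legend("topleft", bty = "n", lwd = 2, col = col,
                   legend = sprintf("-log10(p2) >= %g", x$thresholds))
  invisible(x)
}

#' Write conditional Q-Q curves to TSV files
#'
#' @param x A `conditional_qq` object.
#' @param dir Output directory (one file per stratum).
#' @return Character vector of written paths, invisibly.
#' @export
write_qq_curves <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (cu in x$curves) {
    path <- file.path(dir, sprintf("qq_%s_thr%g.tsv", x$trait,
                                   cu$stratum_threshold))
    write_tsv(cu$points, path)
    paths <- c(paths, path)
  }
  invisible(paths)
}
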
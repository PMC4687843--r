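#' Empirical conditional CDF of the primary trait given the conditioning trait
#'
#' F(p1 | p2) is estimated by counting: the fraction of SNPs with primary
#' p-value at or below `p1` among SNPs with conditioning p-value at or below
#' `p2`. Counts are inclusive (<=). When no SNP falls in the conditioning
#' slice the value is undefined and `NA` is returned ("no data in slice").
#'
#' @param p1,p2 Query p-values (vectors are recycled to a common length).
#' @param panel An `aligned_panel`.
#' @param trait Conditioning trait name or index (default: first).
#' @return Numeric vector of conditional CDF values in \[0, 1\], `NA` where
#'   the conditioning slice is empty.
#' @export
conditional_cdf <- function(p1, p2, panel, trait = 1L) {
  P1 <- panel$p_primary
  P2 <- panel$p_cond[[trait]]
  if (is.null(P2)) stop("unknown conditioning trait: ", trait, call. = FALSE)
  if (length(P1) == 0L) stop("empty panel", call. = FALSE)
  k <- max(length(p1), length(p2))
  p1 <- rep_len(p1, k); p2 <- rep_len(p2, k)
  vapply(seq_len(k), function(i) {
    denom <- sum(P2 <= p2[i])
    if (denom == 0L) return(NA_real_)
    sum(P1 <= p1[i] & P2 <= p2[i]) / denom
  }, 0)
}

#' Pointwise conditional FDR estimate
#'
#' The conditional FDR of the primary trait at (p1, p2) is estimated as
#' `p1 / F(p1 | p2)` with the conditional null proportion conservatively
#' set to 1, clipped at 1. An empty conditioning slice (undefined CDF)
#' yields the maximally conservative value 1.
#'
#' @inheritParams conditional_cdf
#' @return Conditional FDR values in (0, 1\].
#' @export
cfdr_point <- function(p1, p2, panel, trait = 1L) {
  Fhat <- conditional_cdf(p1, p2, panel, trait)
  k <- length(Fhat)
  p1 <- rep_len(p1, k)
  out <- ifelse(is.na(Fhat) | Fhat == 0, 1, pmin(1, p1 / Fhat))
  out
}

#' Unconditional FDR of the primary trait
#'
#' The degenerate case of the conditional estimator with a conditioning
#' slice admitting every SNP: `p1 / ECDF(p1)` over the full panel.
#'
#' @param p1 Query p-values.
#' @param panel An `aligned_panel`.
#' @return FDR values in (0, 1\].
#' @export
uncond_fdr <- function(p1, panel) {
  P1 <- panel$p_primary
  n <- length(P1)
  if (n == 0L) stop("empty panel", call. = FALSE)
  s <- sort(P1)
  cnt <- findInterval(p1, s)   # SNPs with P1 <= p1 (inclusive)
  ifelse(cnt == 0L, 1, pmin(1, p1 / (cnt / n)))
}

#' Build a 2-D conditional FDR lookup table
#'
#' Evaluates the pointwise conditional FDR estimator on a grid of
#' (-log10 p1) x (-log10 p2) breakpoints. Node (a, b) holds the estimate at
#' p1 = 10^-a, p2 = 10^-b over the full panel; nodes whose conditioning
#' slice is empty (or whose numerator count is zero) hold the conservative
#' value 1. An optional monotonization pass applies a running minimum along
#' increasing -log10(p1) at each fixed p2 node (off by default: the raw
#' estimator is reported).
#'
#' @param panel An `aligned_panel`.
#' @param trait Conditioning trait name or index.
#' @param grid_p1 Strictly increasing -log10(p1) breakpoints.
#' @param grid_p2 Strictly increasing -log10(p2) breakpoints.
#' @param monotonize Apply the running-minimum pass along p1?
#' @return Object of class `"cfdr_lookup"`: list with `grid_p1`, `grid_p2`,
#'   `fdr` (matrix, rows = p1 nodes, cols = p2 nodes), `n_at_node` (SNP
#'   count per conditioning slice), `trait`, `monotonized`.
#' @export
build_lookup <- function(panel, trait = 1L,
                         grid_p1 = seq(0, 10, by = 0.1),
                         grid_p2 = seq(0, 10, by = 0.5),
                         monotonize = FALSE) {
  if (any(diff(grid_p1) <= 0) || any(diff(grid_p2) <= 0))
    stop("grids must be strictly increasing in -log10 space", call. = FALSE)
  P1 <- panel$p_primary
  P2 <- panel$p_cond[[trait]]
  if (is.null(P2)) stop("unknown conditioning trait: ", trait, call. = FALSE)
  p1v <- 10^(-grid_p1)
  p2v <- 10^(-grid_p2)
  fdr <- matrix(1, nrow = length(grid_p1), ncol = length(grid_p2))
  n_at_node <- integer(length(grid_p2))
  for (b in seq_along(grid_p2)) {
    slice <- P1[P2 <= p2v[b]]
    m <- length(slice)
    n_at_node[b] <- m
    if (m == 0L) next                      # empty slice -> 1 everywhere
    cnt <- findInterval(p1v, sort(slice))  # inclusive counts of P1 <= p1
    Fhat <- cnt / m
    fdr[, b] <- ifelse(cnt == 0L, 1, pmin(1, p1v / Fhat))
  }
  if (monotonize)
    for (b in seq_along(grid_p2)) fdr[, b] <- cummin(fdr[, b])
  trait_name <- if (is.numeric(trait)) names(panel$p_cond)[trait] else trait
  structure(list(grid_p1 = grid_p1, grid_p2 = grid_p2, fdr = fdr,
                 n_at_node = n_at_node, trait = trait_name,
                 monotonized = monotonize),
            class = "cfdr_lookup")
}

#' @export
print.cfdr_lookup <- function(x, ...) {
  cat(sprintf("2-D conditional FDR lookup | trait: %s | %d x %d nodes%s\n",
              x$trait, length(x$grid_p1), length(x$grid_p2),
              if (x$monotonized) " (monotonized)" else ""))
  invisible(x)
}

#' Assign per-SNP conditional FDR by interpolation into a lookup table
#'
#' Bilinear interpolation of -log10(FDR) over the (-log10 p1, -log10 p2)
#' grid, back-transformed to the FDR scale. Interpolating on the -log10
#' scale keeps the scheme numerically stable across the many orders of
#' magnitude the table spans. Queries beyond the grid are clamped to the
#' boundary nodes; queries exactly at a node reproduce the node value.
#'
#' @param lookup A `cfdr_lookup`.
#' @param p1,p2 Query p-values (recycled to a common length).
#' @return Interpolated conditional FDR values in (0, 1\].
#' @export
interpolate_fdr <- function(lookup, p1, p2) {
  g1 <- lookup$grid_p1; g2 <- lookup$grid_p2
  L <- -log10(lookup$fdr)
  k <- max(length(p1), length(p2))
  a <- pmin(max(g1), pmax(min(g1), -log10(rep_len(p1, k))))
  b <- pmin(max(g2), pmax(min(g2), -log10(rep_len(p2, k))))
  i <- pmin(findInterval(a, g1), length(g1) - 1L)
  j <- pmin(findInterval(b, g2), length(g2) - 1L)
  t <- (a - g1[i]) / (g1[i + 1L] - g1[i])
  u <- (b - g2[j]) / (g2[j + 1L] - g2[j])
  n1 <- length(g1)
  idx <- function(ii, jj) (jj - 1L) * n1 + ii
  Li <- (1 - t) * (1 - u) * L[idx(i, j)] +
        t       * (1 - u) * L[idx(i + 1L, j)] +
        (1 - t) * u       * L[idx(i, j + 1L)] +
        t       * u       * L[idx(i + 1L, j + 1L)]
  10^(-Li)
}

#' Per-SNP conditional FDR summary across conditioning traits
#'
#' Assigns every panel SNP its conditional FDR against each conditioning
#' trait (by lookup interpolation), the minimum across traits, the driving
#' trait attaining that minimum (ties broken by lookup order), the
#' unconditional primary-trait FDR, and the significance call at the
#' configured threshold.
#'
#' @param panel An `aligned_panel`.
#' @param lookups Named list of `cfdr_lookup`s, one per conditioning trait,
#'   all built on the same primary trait.
#' @param threshold Significance threshold on the minimum conditional FDR
#'   (default 0.01).
#' @return A `data.frame` of class `"cfdr_result"` with columns `rsid`,
#'   `chrom`, `pos`, `p_primary`, `uncond_fdr`, one `cfdr_<trait>` column
#'   per conditioning trait, `min_cfdr`, `driving_trait`, `significant`.
#' @export
cfdr_summarize <- function(panel, lookups, threshold = 0.01) {
  if (is.null(names(lookups)))
    names(lookups) <- vapply(lookups, `[[`, "", "trait")
  missing_tr <- setdiff(names(lookups), names(panel$p_cond))
  if (length(missing_tr) > 0L)
    stop("lookup trait(s) not in panel: ", paste(missing_tr, collapse = ", "),
         call. = FALSE)
  p1 <- panel$p_primary
  mat <- vapply(names(lookups), function(tr) {
    interpolate_fdr(lookups[[tr]], p1, panel$p_cond[[tr]])
  }, numeric(length(p1)))
  mat <- matrix(mat, nrow = length(p1),
                dimnames = list(NULL, names(lookups)))
  pick <- max.col(-mat, ties.method = "first")
  min_cfdr <- mat[cbind(seq_len(nrow(mat)), pick)]
  out <- data.frame(rsid = panel$snps$rsid, chrom = panel$snps$chrom,
                    pos = panel$snps$pos, p_primary = p1,
                    uncond_fdr = uncond_fdr(p1, panel),
                    stringsAsFactors = FALSE)
  for (tr in names(lookups)) out[[paste0("cfdr_", tr)]] <- mat[, tr]
  out$min_cfdr <- min_cfdr
  out$driving_trait <- names(lookups)[pick]
  out$significant <- min_cfdr < threshold
  attr(out, "threshold") <- threshold
  class(out) <- c("cfdr_result", "data.frame")
  out
}

#' Write a lookup table as a TSV matrix with grid headers
#'
#' @param lookup A `cfdr_lookup`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_lookup <- function(lookup, path) {
  df <- as.data.frame(lookup$fdr)
  names(df) <- sprintf("p2_neglog_%g", lookup$grid_p2)
  df <- cbind(p1_neglog = lookup$grid_p1, df)
  write_tsv(df, path)
}
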
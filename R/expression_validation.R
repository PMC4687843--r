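#' Covariate-adjusted Pearson correlation (partial correlation)
#'
#' Residualizes both variables on an intercept plus the covariates by least
#' squares, then computes the Pearson correlation of the residuals. The
#' two-sided p-value uses a t-distribution with n - 2 - k degrees of
#' freedom, where k is the number of covariates.
#'
#' @param x,y Numeric vectors of equal length.
#' @param covariates Numeric matrix (or data.frame) with one row per
#'   sample, e.g. cbind(age, bmi).
#' @return List with `r`, `p`, `df`, `n`. Zero residual variance in either
#'   variable yields `r = NA`, `p = NA` with a warning.
#' @export
adjusted_correlation <- function(x, y, covariates) {
  covariates <- as.matrix(covariates)
  n <- length(x)
  k <- ncol(covariates)
  stopifnot(length(y) == n, nrow(covariates) == n)
  if (n < k + 4L)
    stop("need at least 4 samples more than covariates (n = ", n,
         ", covariates = ", k, ")", call. = FALSE)
  X <- cbind(1, covariates)
  qx <- qr(X)
  if (qx$rank < ncol(X))
    stop("rank-deficient covariate matrix", call. = FALSE)
  rx <- qr.resid(qx, x)
  ry <- qr.resid(qx, y)
  tol <- 1e-12 * n
  if (sum(rx^2) <= tol * max(1, sum(x^2)) ||
      sum(ry^2) <= tol * max(1, sum(y^2))) {
    warning("zero residual variance after covariate adjustment: ",
            "correlation undefined", call. = FALSE)
    return(list(r = NA_real_, p = NA_real_, df = n - 2L - k, n = n))
  }
  r <- stats::cor(rx, ry)
  df <- n - 2L - k
  tstat <- r * sqrt(df / (1 - r^2))
  p <- 2 * stats::pt(-abs(tstat), df = df)
  list(r = r, p = p, df = df, n = n)
}

#' Expression validation of a candidate gene set
#'
#' For each submitted gene symbol, correlates its (log2) expression with
#' the phenotype after adjusting both for age and BMI, and calls nominal
#' significance at `alpha`. Genes without a probe in the expression set are
#' reported `NA` (undetected). Genes measured by several probes use the
#' probe with the largest absolute adjusted correlation by default
#' (`probe_rule = "max_abs_r"`; `"first"` keeps the first probe in the
#' map).
#'
#' @param gene_symbols Character vector of candidate genes.
#' @param expr An `expression_set` (see [simulate_expression()] /
#'   [read_expression_set()]).
#' @param alpha Nominal significance level (default 0.05).
#' @param probe_rule Multi-probe collapsing rule.
#' @return Object of class `"expr_validation"`: list with `table` (per-gene
#'   probe, r, p, detected, significant) and `summary` (counts plus the
#'   significant fraction over detected genes and over submitted genes).
#' @export
validate_gene_set <- function(gene_symbols, expr, alpha = 0.05,
                              probe_rule = c("max_abs_r", "first")) {
  probe_rule <- match.arg(probe_rule)
  stopifnot(alpha > 0, alpha < 1)
  covs <- cbind(age = expr$samples$age, bmi = expr$samples$bmi)
  pheno <- expr$samples$pheno
  rows <- lapply(gene_symbols, function(gene) {
    probes <- expr$probes$probe_id[expr$probes$symbol == gene]
    if (length(probes) == 0L)
      return(data.frame(gene = gene, probe = NA_character_, r = NA_real_,
                        p = NA_real_, detected = FALSE, significant = FALSE,
                        stringsAsFactors = FALSE))
    fits <- lapply(probes, function(pr)
      adjusted_correlation(expr$matrix[pr, ], pheno, covs))
    if (length(probes) > 1L && probe_rule == "max_abs_r") {
      pick <- which.max(vapply(fits, function(f) abs(f$r), 0))
      message("validate_gene_set: gene ", gene, " has ", length(probes),
              " probes; keeping ", probes[pick], " (max |r|)")
    } else pick <- 1L
    f <- fits[[pick]]
    data.frame(gene = gene, probe = probes[pick], r = f$r, p = f$p,
               detected = TRUE, significant = is.finite(f$p) & f$p < alpha,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  n_sub <- nrow(tab); n_det <- sum(tab$detected); n_sig <- sum(tab$significant)
  structure(list(
    table = tab,
    summary = list(n_submitted = n_sub, n_detected = n_det,
                   n_significant = n_sig,
                   frac_of_detected = if (n_det > 0) n_sig / n_det else NA_real_,
                   frac_of_submitted = if (n_sub > 0) n_sig / n_sub else NA_real_,
                   alpha = alpha)),
    class = "expr_validation")
}

#' @export
print.expr_validation <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Expression validation: %d/%d genes detected, %d significant at alpha = %g\n",
              s$n_detected, s$n_submitted, s$n_significant, s$alpha))
  cat(sprintf("  significant fraction: %.3f of detected, %.3f of submitted\n",
              s$frac_of_detected, s$frac_of_submitted))
  invisible(x)
}

#' Read an expression set from TSV files
#'
#' @param expr_path Probe x sample matrix TSV (first column `PROBE`).
#' @param samples_path Sample sheet TSV with columns
#'   `SAMPLE PHENO AGE BMI`.
#' @param probes_path Probe-to-gene map TSV with columns `PROBE SYMBOL`.
#' @return An `expression_set`: list with `matrix` (probes x samples),
#'   `probes` (probe_id, symbol), `samples` (sample_id, pheno, age, bmi).
#' @export
read_expression_set <- function(expr_path, samples_path, probes_path) {
  em <- utils::read.table(expr_path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  mat <- as.matrix(em[, -1, drop = FALSE])
  rownames(mat) <- em[[1]]
  ss <- utils::read.table(samples_path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  pm <- utils::read.table(probes_path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  stopifnot(all(c("SAMPLE", "PHENO", "AGE", "BMI") %in% names(ss)),
            all(c("PROBE", "SYMBOL") %in% names(pm)))
  mat <- mat[, as.character(ss$SAMPLE), drop = FALSE]
  if (any(!is.finite(mat))) stop("non-finite expression values", call. = FALSE)
  if (anyNA(ss$PHENO) || anyNA(ss$AGE) || anyNA(ss$BMI))
    stop("missing phenotype or covariates in sample sheet", call. = FALSE)
  structure(list(matrix = mat,
                 probes = data.frame(probe_id = as.character(pm$PROBE),
                                     symbol = as.character(pm$SYMBOL),
                                     stringsAsFactors = FALSE),
                 samples = data.frame(sample_id = as.character(ss$SAMPLE),
                                      pheno = ss$PHENO, age = ss$AGE,
                                      bmi = ss$BMI, stringsAsFactors = FALSE)),
            class = "expression_set")
}

#' Write an expression set to TSV files
#'
#' Inverse of [read_expression_set()]; used to stage simulated expression
#' data for the pipeline.
#'
#' @param expr An `expression_set`.
#' @param dir Output directory.
#' @return Named list of paths (`matrix`, `samples`, `probes`), invisibly.
#' @export
write_expression_set <- function(expr, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(matrix = file.path(dir, "expression_matrix.tsv"),
                samples = file.path(dir, "expression_samples.tsv"),
                probes = file.path(dir, "expression_probes.tsv"))
  em <- data.frame(PROBE = rownames(expr$matrix), expr$matrix,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(em, paths$matrix)
  write_tsv(data.frame(SAMPLE = expr$samples$sample_id,
                       PHENO = expr$samples$pheno, AGE = expr$samples$age,
                       BMI = expr$samples$bmi), paths$samples)
  write_tsv(data.frame(PROBE = expr$probes$probe_id,
                       SYMBOL = expr$probes$symbol), paths$probes)
  invisible(paths)
}
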
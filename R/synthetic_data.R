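#' Configuration for the two-trait GWAS simulator
#'
#' The generator draws per-SNP z-scores for two traits from a four-component
#' mixture: null, trait-1-only, trait-2-only, and pleiotropic SNPs.
#' Non-null SNPs receive a normal mean shift on the z scale (shared
#' standardized draw for pleiotropic SNPs, scaled by each trait's effect
#' SD, which induces the positive cross-trait dependence of small p-values
#' that conditional FDR leverages). Optional block LD is a per-block shared
#' latent factor (compound symmetry): loading sqrt(within_block_r) gives
#' pairwise z correlation ~ within_block_r. Per-trait genomic inflation
#' multiplies z by sqrt(lambda).
#'
#' @param n_snps Total SNP count.
#' @param pi_null,pi_1,pi_2,pi_pleio Mixture proportions (sum to 1).
#' @param sigma1,sigma2 Effect SDs on the z scale for non-null SNPs.
#' @param lambda1,lambda2 Genomic inflation factors per trait.
#' @param ld_block_size SNPs per LD block (1 = independent SNPs).
#' @param within_block_r Within-block pairwise z correlation in \[0, 0.99\].
#' @param intergenic_frac Fraction of null SNPs annotated `intergenic`
#'   (intergenic SNPs are depleted of association, mirroring the annotation
#'   from which lambda_GC is estimated).
#' @param seed Integer seed; all randomness flows from it.
#' @return Validated list of class `"sim_config"`.
#' @export
sim_config <- function(n_snps = 100000L, pi_null = 0.95, pi_1 = 0.02,
                       pi_2 = 0.02, pi_pleio = 0.01, sigma1 = 3, sigma2 = 3,
                       lambda1 = 1, lambda2 = 1, ld_block_size = 1L,
                       within_block_r = 0, intergenic_frac = 0.5,
                       seed = 1L) {
  pis <- c(pi_null, pi_1, pi_2, pi_pleio)
  if (any(pis < 0) || abs(sum(pis) - 1) > 1e-12)
    stop("mixture proportions must be nonnegative and sum to 1", call. = FALSE)
  if (sigma1 <= 0 || sigma2 <= 0) stop("sigmas must be > 0", call. = FALSE)
  if (within_block_r < 0 || within_block_r > 0.99)
    stop("within_block_r must lie in [0, 0.99]", call. = FALSE)
  structure(list(n_snps = as.integer(n_snps), pi_null = pi_null, pi_1 = pi_1,
                 pi_2 = pi_2, pi_pleio = pi_pleio, sigma1 = sigma1,
                 sigma2 = sigma2, lambda1 = lambda1, lambda2 = lambda2,
                 ld_block_size = as.integer(ld_block_size),
                 within_block_r = within_block_r,
                 intergenic_frac = intergenic_frac, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a two-trait summary-statistics panel with known truth
#'
#' Produces two per-trait summary-statistics tables (`SNP CHR BP P DIR
#' CAT`), the within-block LD triplets (emitted when the theoretical
#' r-squared exceeds 0.05), and the per-SNP truth labels. p-values are the
#' two-sided normal tail probabilities of the simulated z magnitudes, with
#' the sign recorded in the direction column, so that null p-values are
#' uniform on (0, 1] — the sampling model under which the FDR estimator is
#' calibrated. Deterministic under a fixed seed.
#'
#' @param config A [sim_config()].
#' @return List of class `"sim_panel"`: `sumstats` (named list of two
#'   `sumstats` tables), `ld` (rsid_a, rsid_b, r2), `truth` (rsid, label in
#'   null/t1/t2/pleio, mu1, mu2), `config`.
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_snps
  label <- sample(c("null", "t1", "t2", "pleio"), n, replace = TRUE,
                  prob = c(config$pi_null, config$pi_1, config$pi_2,
                           config$pi_pleio))
  u <- stats::rnorm(n)   # standardized effect draw, shared for pleio SNPs
  u1 <- stats::rnorm(n)  # trait-specific draws
  u2 <- stats::rnorm(n)
  mu1 <- ifelse(label == "pleio", config$sigma1 * u,
                ifelse(label == "t1", config$sigma1 * u1, 0))
  mu2 <- ifelse(label == "pleio", config$sigma2 * u,
                ifelse(label == "t2", config$sigma2 * u2, 0))
  bs <- config$ld_block_size
  block <- rep(seq_len(ceiling(n / bs)), each = bs)[seq_len(n)]
  r <- config$within_block_r
  eps <- function() {
    if (r > 0) {
      f <- stats::rnorm(max(block))
      sqrt(r) * f[block] + sqrt(1 - r) * stats::rnorm(n)
    } else stats::rnorm(n)
  }
  z1 <- (mu1 + eps()) * sqrt(config$lambda1)
  z2 <- (mu2 + eps()) * sqrt(config$lambda2)
  # genomic layout: blocks laid out consecutively, round-robin over 22
  # autosomes, 5 kb SNP spacing so each block is intra-chromosomal
  chrom <- as.character((block - 1L) %% 22L + 1L)
  pos_in_chr <- stats::ave(seq_len(n), chrom, FUN = seq_along)
  pos <- pos_in_chr * 5000
  rsid <- sprintf("rs%07d", seq_len(n))
  category <- rep("genic", n)
  is_null <- label == "null"
  category[is_null & stats::runif(n) < config$intergenic_frac] <- "intergenic"
  make_tab <- function(z) {
    p <- pmax(P_FLOOR, 2 * stats::pnorm(abs(z), lower.tail = FALSE))
    df <- data.frame(rsid = rsid, chrom = chrom, pos = pos, p = p,
                     direction = ifelse(z >= 0, 1L, -1L),
                     maf = NA_real_, category = category,
                     stringsAsFactors = FALSE)
    class(df) <- c("sumstats", "data.frame")
    df
  }
  ld <- data.frame(rsid_a = character(0), rsid_b = character(0),
                   r2 = numeric(0), stringsAsFactors = FALSE)
  if (bs > 1L && r^2 > 0.05) {
    pairs <- do.call(rbind, lapply(split(seq_len(n), block), function(idx) {
      if (length(idx) < 2L) return(NULL)
      cmb <- utils::combn(idx, 2L)
      data.frame(rsid_a = rsid[cmb[1, ]], rsid_b = rsid[cmb[2, ]],
                 r2 = r^2, stringsAsFactors = FALSE)
    }))
    rownames(pairs) <- NULL
    ld <- pairs
  }
  structure(list(
    sumstats = list(trait1 = make_tab(z1), trait2 = make_tab(z2)),
    ld = ld,
    truth = data.frame(rsid = rsid, label = label, mu1 = mu1, mu2 = mu2,
                       stringsAsFactors = FALSE),
    config = config), class = "sim_panel")
}

#' Simulate a log2 expression set with planted phenotype correlations
#'
#' Phenotype, age and BMI are drawn independently per sample; each gene's
#' expression is planted_r times the standardized phenotype plus
#' sqrt(1 - r^2) noise, contaminated with age and BMI loadings, then
#' shifted and scaled to a log2-intensity-like range. Because the
#' covariates are independent of the phenotype, the partial correlation
#' (given age and BMI) of each gene with the phenotype equals `planted_r`.
#'
#' @param n_genes Number of genes (one probe each).
#' @param n_samples Number of samples (default 84, a typical biopsy cohort
#'   size).
#' @param planted_r Planted partial correlation(s), recycled over genes;
#'   each in (-1, 1).
#' @param age_loading,bmi_loading Contamination loadings on standardized
#'   age and BMI.
#' @param seed Integer seed.
#' @return An `expression_set` with an extra `planted_r` element.
#' @export
simulate_expression <- function(n_genes = 100L, n_samples = 84L,
                                planted_r = 0, age_loading = 0.3,
                                bmi_loading = 0.3, seed = 1L) {
  planted_r <- rep_len(planted_r, n_genes)
  if (any(abs(planted_r) >= 1))
    stop("planted_r must lie in (-1, 1)", call. = FALSE)
  set.seed(seed)
  pheno <- stats::rnorm(n_samples, mean = 0.85, sd = 0.12)  # BMD-like, g/cm^2
  age <- stats::rnorm(n_samples, mean = 65, sd = 8)
  bmi <- stats::rnorm(n_samples, mean = 26, sd = 4)
  zp <- as.numeric(scale(pheno)); za <- as.numeric(scale(age))
  zb <- as.numeric(scale(bmi))
  mat <- t(vapply(seq_len(n_genes), function(g) {
    r <- planted_r[g]
    sig <- r * zp + sqrt(1 - r^2) * stats::rnorm(n_samples)
    7 + 1.5 * (sig + age_loading * za + bmi_loading * zb)
  }, numeric(n_samples)))
  probe_id <- sprintf("%06d_at", 200000L + seq_len(n_genes))
  symbol <- sprintf("GENE%04d", seq_len(n_genes))
  rownames(mat) <- probe_id
  colnames(mat) <- sprintf("S%03d", seq_len(n_samples))
  structure(list(matrix = mat,
                 probes = data.frame(probe_id = probe_id, symbol = symbol,
                                     stringsAsFactors = FALSE),
                 samples = data.frame(sample_id = colnames(mat), pheno = pheno,
                                      age = age, bmi = bmi,
                                      stringsAsFactors = FALSE),
                 planted_r = planted_r),
            class = "expression_set")
}

#' Simulate a gene table and known-locus lists
#'
#' Genes are placed as pairwise-disjoint intervals (each gene inside its
#' own equal-width slot of the chromosome). A configurable fraction of the
#' gene symbols, and of the supplied rsids, is exported as the "known"
#' list, to exercise novelty classification.
#'
#' @param n_genes Number of genes.
#' @param chrom_lengths Named vector of chromosome lengths in bp.
#' @param known_frac Fraction of gene symbols (and rsids) marked known.
#' @param rsids Optional rsid pool from which known rsids are drawn.
#' @param seed Integer seed.
#' @return List with `genes` (gene table), `known_genes`, `known_rsids`.
#' @export
simulate_genes <- function(n_genes = 200L,
                           chrom_lengths = stats::setNames(
                             rep(25e6, 22), as.character(1:22)),
                           known_frac = 0, rsids = NULL, seed = 1L) {
  set.seed(seed)
  chroms <- rep(names(chrom_lengths), length.out = n_genes)
  tab <- do.call(rbind, lapply(unique(chroms), function(ch) {
    k <- sum(chroms == ch)
    slot <- floor(chrom_lengths[[ch]] / k)
    width <- pmin(slot - 2L, floor(stats::runif(k, 5e3, 5e4)))
    start0 <- (seq_len(k) - 1L) * slot + 1L
    offset <- floor(stats::runif(k, 0, slot - width - 1))
    data.frame(chrom = ch, start = start0 + offset,
               end = start0 + offset + width, stringsAsFactors = FALSE)
  }))
  tab$symbol <- sprintf("GENE%04d", seq_len(nrow(tab)))
  tab$strand <- sample(c("+", "-"), nrow(tab), replace = TRUE)
  rownames(tab) <- NULL
  known_genes <- if (known_frac > 0)
    sort(sample(tab$symbol, floor(known_frac * nrow(tab)))) else character(0)
  known_rsids <- if (known_frac > 0 && !is.null(rsids))
    sort(sample(rsids, floor(known_frac * length(rsids)))) else character(0)
  list(genes = tab, known_genes = known_genes, known_rsids = known_rsids)
}

#' Write simulated inputs to the file formats the analysis consumes
#'
#' @param sim A `sim_panel`.
#' @param dir Output directory.
#' @return Named list of written paths, invisibly.
#' @export
write_sim_panel <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  for (tr in names(sim$sumstats)) {
    tab <- sim$sumstats[[tr]]
    df <- data.frame(SNP = tab$rsid, CHR = tab$chrom, BP = tab$pos,
                     P = sprintf("%.17g", tab$p),
                     DIR = ifelse(tab$direction >= 0, "+", "-"),
                     CAT = tab$category, stringsAsFactors = FALSE)
    paths[[tr]] <- file.path(dir, paste0(tr, ".tsv"))
    write_tsv(df, paths[[tr]])
  }
  ld <- data.frame(SNP_A = sim$ld$rsid_a, SNP_B = sim$ld$rsid_b,
                   R2 = sim$ld$r2, stringsAsFactors = FALSE)
  paths$ld <- file.path(dir, "ld.tsv")
  write_tsv(ld, paths$ld)
  paths$truth <- file.path(dir, "truth.tsv")
  write_tsv(sim$truth, paths$truth)
  invisible(paths)
}
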
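# Build an aligned panel directly from p-value vectors (bypassing file IO)
# for unit tests of the conditional statistics.
make_panel <- function(p1, p_cond, chrom = NULL, pos = NULL, rsid = NULL,
                       direction = NULL) {
  n <- length(p1)
  if (!is.list(p_cond)) p_cond <- list(trait2 = p_cond)
  if (is.null(names(p_cond)))
    names(p_cond) <- paste0("trait", seq_along(p_cond) + 1L)
  if (is.null(rsid)) rsid <- sprintf("rs%04d", seq_len(n))
  if (is.null(chrom)) chrom <- rep("1", n)
  if (is.null(pos)) pos <- seq_len(n) * 1000
  if (is.null(direction)) direction <- rep(NA_integer_, n)
  structure(list(
    snps = data.frame(rsid = rsid, chrom = chrom, pos = pos,
                      direction = direction, stringsAsFactors = FALSE),
    p_primary = p1, p_cond = p_cond,
    trait_names = c("trait1", names(p_cond)),
    gc_applied = stats::setNames(rep(FALSE, length(p_cond) + 1L),
                                 c("trait1", names(p_cond)))),
    class = "aligned_panel")
}

# Write a minimal summary-statistics file; `rows` is a character vector of
# data lines under a "SNP CHR BP P ..." header.
write_sumstats_file <- function(rows, header = "SNP\tCHR\tBP\tP",
                                path = tempfile(fileext = ".tsv")) {
  writeLines(c(header, rows), path)
  path
}

# Stratum ECDF at a nominal p cut: fraction of primary p-values <= p_cut
# among SNPs whose conditioning p-value satisfies -log10(p2) >= thr.
stratum_ecdf <- function(panel, trait, thr, p_cut) {
  idx <- -log10(panel$p_cond[[trait]]) >= thr
  if (!any(idx)) return(NA_real_)
  mean(panel$p_primary[idx] <= p_cut)
}

sim_two_trait_panel <- function(config) {
  sim <- simulate_panel(config)
  panel <- suppressMessages(intersect_traits(
    sim$sumstats$trait1, list(trait2 = sim$sumstats$trait2), "trait1"))
  list(sim = sim, panel = panel,
       label = sim$truth$label[match(panel$snps$rsid, sim$truth$rsid)])
}
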
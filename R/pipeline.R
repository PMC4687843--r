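#' Default run configuration
#'
#' All thresholds default to the values used throughout the analysis:
#' conditional FDR significance 0.01, Q-Q stratum ladder (0, 1, 2, 3) on
#' -log10(p2), Q-Q display ceiling 7.3 (-log10 of 5e-8), LD clumping
#' r-squared 0.2, expression significance 0.05.
#'
#' @return Named list of configuration keys.
#' @export
default_run_config <- function() {
  list(
    primary = NULL,              # path to primary-trait sumstats TSV
    primary_name = "primary",
    conditioners = list(),       # named list of paths
    ld = NULL,                   # LD triplet TSV
    genes = NULL,                # gene table TSV
    known_loci = NULL,           # known-locus TSV (RSID, GENE)
    expression = NULL,           # list(matrix=, samples=, probes=) of paths
    out_dir = "pleiocfdr_results",
    cfdr_threshold = 0.01,
    qq_thresholds = c(0, 1, 2, 3),
    qq_focus_max_logp = 7.3,
    clump_r2 = 0.2,
    expression_alpha = 0.05,
    grid_p1 = seq(0, 10, by = 0.1),
    grid_p2 = seq(0, 10, by = 0.5),
    monotonize_lookup = FALSE,
    qq_on_raw_p = FALSE,
    probe_rule = "max_abs_r",
    render_figures = FALSE,
    seed = 1L,
    column_map = list()
  )
}

#' Read a run configuration from a YAML file
#'
#' Keys present in the file override [default_run_config()].
#'
#' @param path YAML file path.
#' @return Merged configuration list.
#' @export
read_run_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- utils::modifyList(default_run_config(), user)
  cfg
}

#' Run the full conditional FDR analysis pipeline
#'
#' Executes, in order: genomic control per trait -> SNP intersection ->
#' conditional Q-Q curves -> 2-D lookup construction -> per-SNP cFDR
#' assignment -> LD clumping of significant SNPs -> nearest-gene
#' annotation and novelty classification -> optional expression
#' validation. Writes per-stage TSVs, a locus summary table, a
#' machine-readable JSON run manifest, and (optionally) figures.
#'
#' @param config Configuration list (see [default_run_config()]) or path
#'   to a YAML file.
#' @return Invisibly, a list with `panel`, `qq`, `lookups`, `cfdr`,
#'   `loci`, `expression`, `manifest`, `out_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  cfg <- utils::modifyList(default_run_config(), config)
  if (is.null(cfg$primary) || length(cfg$conditioners) == 0L)
    stop("config must provide 'primary' and at least one conditioner",
         call. = FALSE)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  manifest <- list(seed = cfg$seed,
                   package_version = as.character(utils::packageVersion("pleiocfdr")),
                   inputs = list(primary = cfg$primary,
                                 conditioners = cfg$conditioners,
                                 ld = cfg$ld, genes = cfg$genes,
                                 known_loci = cfg$known_loci),
                   counts = list(), lambda_gc = list())

  ## 1. read + genomic control
  tabs <- stage("read", {
    pri <- read_sumstats(cfg$primary, cfg$column_map)
    cond <- lapply(cfg$conditioners, read_sumstats, column_map = cfg$column_map)
    c(stats::setNames(list(pri), cfg$primary_name), cond)
  })
  manifest$counts$snps_read <- lapply(tabs, nrow)
  raw_tabs <- tabs
  tabs <- stage("genomic_control", lapply(tabs, gc_correct_sumstats))
  manifest$lambda_gc <- lapply(tabs, function(t) attr(t, "gc")$lambda_gc)
  write_tsv(data.frame(trait = names(tabs),
                       lambda_gc = unlist(manifest$lambda_gc),
                       n_intergenic = vapply(tabs, function(t)
                         attr(t, "gc")$n_intergenic, 0L)),
            file.path(cfg$out_dir, "gc_estimates.tsv"))

  ## 2. intersection
  panel <- stage("intersect", intersect_traits(
    tabs[[1]], tabs[-1], primary_name = cfg$primary_name))
  panel$gc_applied[] <- TRUE
  manifest$counts$snps_intersected <- length(panel$p_primary)

  ## 3. conditional Q-Q
  qq_panel <- panel
  if (cfg$qq_on_raw_p) {
    qq_panel <- stage("qq_raw", intersect_traits(
      raw_tabs[[1]], raw_tabs[-1], primary_name = cfg$primary_name))
  }
  qq <- stage("conditional_qq", lapply(names(panel$p_cond), function(tr)
    conditional_qq(qq_panel, tr, cfg$qq_thresholds, cfg$qq_focus_max_logp)))
  names(qq) <- names(panel$p_cond)
  for (tr in names(qq)) write_qq_curves(qq[[tr]], file.path(cfg$out_dir, "qq"))

  ## 4. lookup tables
  lookups <- stage("build_lookup", lapply(names(panel$p_cond), function(tr)
    build_lookup(panel, tr, cfg$grid_p1, cfg$grid_p2,
                 monotonize = cfg$monotonize_lookup)))
  names(lookups) <- names(panel$p_cond)
  for (tr in names(lookups))
    write_lookup(lookups[[tr]],
                 file.path(cfg$out_dir, sprintf("lookup_%s.tsv", tr)))

  ## 5. per-SNP cFDR
  cfdr <- stage("cfdr", cfdr_summarize(panel, lookups, cfg$cfdr_threshold))
  write_tsv(format_cfdr_table(cfdr), file.path(cfg$out_dir, "cfdr.tsv"))
  manifest$counts$snps_significant <- sum(cfdr$significant)

  ## 6-8. clumping, annotation, novelty
  loci <- NULL
  if (!is.null(cfg$ld) && any(cfdr$significant)) {
    edges <- stage("read_ld", read_ld_triplets(cfg$ld))
    sig <- cfdr[cfdr$significant,
                c("rsid", "chrom", "pos", "p_primary", "min_cfdr",
                  "driving_trait", "uncond_fdr")]
    names(sig)[names(sig) == "min_cfdr"] <- "cfdr"
    names(sig)[names(sig) == "p_primary"] <- "p"
    leads <- stage("clump", greedy_lead_selection(sig, edges, cfg$clump_r2))
    loci <- stage("clump", assign_blocks(leads, sig, edges, cfg$clump_r2))
    manifest$counts$loci <- nrow(loci)
    manifest$counts$leads <- length(leads)
    if (!is.null(cfg$genes)) {
      genes <- stage("annotate", read_gene_table(cfg$genes))
      loci <- stage("annotate", annotate_loci(loci, cfdr, genes))
      known <- if (!is.null(cfg$known_loci))
        stage("novelty", read_known_loci(cfg$known_loci))
      else list(rsids = character(0), genes = character(0))
      loci <- stage("novelty", novelty_filter(loci, known$rsids, known$genes))
      manifest$counts$novel_loci <- sum(loci$novelty == "novel")
      manifest$counts$complex_loci <- sum(loci$loc_class == "complex")
    }
    write_tsv(as.data.frame(loci), file.path(cfg$out_dir, "loci.tsv"))
  }

  ## 9. expression validation
  expval <- NULL
  if (!is.null(cfg$expression) && !is.null(loci) && "genes" %in% names(loci)) {
    expr <- stage("expression", read_expression_set(
      cfg$expression$matrix, cfg$expression$samples, cfg$expression$probes))
    genes_to_test <- unique(unlist(locus_gene_list(loci)))
    expval <- stage("expression", validate_gene_set(
      genes_to_test, expr, cfg$expression_alpha, cfg$probe_rule))
    write_tsv(expval$table, file.path(cfg$out_dir, "expression_validation.tsv"))
    manifest$counts$genes_tested <- expval$summary$n_submitted
    manifest$counts$genes_significant <- expval$summary$n_significant
  }

  ## locus summary table in the shape of a published locus table
  if (!is.null(loci)) {
    write_tsv(locus_report(loci, cfdr, panel, expval),
              file.path(cfg$out_dir, "locus_table.tsv"))
  }

  manifest$resolved_config <- cfg[setdiff(names(cfg), "column_map")]
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  result <- list(panel = panel, qq = qq, lookups = lookups, cfdr = cfdr,
                 loci = loci, expression = expval, manifest = manifest,
                 out_dir = cfg$out_dir)
  if (isTRUE(cfg$render_figures)) render_figures(result, cfg$out_dir)
  invisible(result)
}

# fixed-precision scientific formatting keeps reruns byte-identical
format_cfdr_table <- function(cfdr) {
  df <- as.data.frame(cfdr)
  num <- vapply(df, is.numeric, TRUE) & !names(df) %in% c("pos")
  for (cl in names(df)[num]) df[[cl]] <- sprintf("%.6e", df[[cl]])
  df
}

# one row per locus: lead SNP, genes, location, p / FDR / cFDR of the lead,
# Wald statistic, driving phenotype, expression correlation when available
locus_report <- function(loci, cfdr, panel, expval = NULL) {
  idx <- match(loci$lead, cfdr$rsid)
  dir <- panel$snps$direction[match(loci$lead, panel$snps$rsid)]
  wald <- p_to_z(cfdr$p_primary[idx], dir)
  out <- data.frame(
    locus = loci$locus_id,
    snp = loci$lead,
    gene_symbol = if ("genes" %in% names(loci)) loci$genes else NA_character_,
    map_loc = paste0(loci$chrom, ":", format(loci$pos, scientific = FALSE,
                                             trim = TRUE)),
    p_value = sprintf("%.6e", cfdr$p_primary[idx]),
    fdr = sprintf("%.6e", cfdr$uncond_fdr[idx]),
    min_cond_fdr = sprintf("%.6e", loci$min_cfdr),
    wald_stat = round(wald, 2),
    driving_phenotype = loci$driving_trait,
    loc_class = if ("loc_class" %in% names(loci)) loci$loc_class
                else NA_character_,
    novelty = if ("novelty" %in% names(loci)) loci$novelty else NA_character_,
    stringsAsFactors = FALSE)
  if (!is.null(expval)) {
    first_gene <- vapply(locus_gene_list(loci),
                         function(g) if (length(g)) g[1] else NA_character_, "")
    m <- match(first_gene, expval$table$gene)
    out$expression_r <- round(expval$table$r[m], 3)
  }
  out
}

#' Render the analysis figures
#'
#' Produces one conditional Q-Q figure per conditioning trait (curves per
#' stratum, dotted null diagonal), a conditional FDR Manhattan plot
#' (-log10 of the minimum conditional FDR by genomic position; significant
#' SNPs enlarged, lead SNPs outlined in black and labelled with their
#' nearest gene), and one lookup heatmap per conditioning trait (colour =
#' conditional FDR).
#'
#' @param result Result list from [run_pipeline()].
#' @param dir Output directory for PNG files.
#' @return Character vector of written files, invisibly.
#' @export
render_figures <- function(result, dir = result$out_dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  for (tr in names(result$qq)) {
    f <- file.path(dir, sprintf("fig_qq_%s.png", tr))
    grDevices::png(f, width = 900, height = 700, res = 110)
    plot(result$qq[[tr]])
    grDevices::dev.off()
    written <- c(written, f)
  }
  f <- file.path(dir, "fig_manhattan.png")
  grDevices::png(f, width = 1400, height = 600, res = 110)
  plot_manhattan(result$cfdr, result$loci)
  grDevices::dev.off()
  written <- c(written, f)
  for (tr in names(result$lookups)) {
    f <- file.path(dir, sprintf("fig_lookup_%s.png", tr))
    grDevices::png(f, width = 800, height = 700, res = 110)
    plot_lookup(result$lookups[[tr]])
    grDevices::dev.off()
    written <- c(written, f)
  }
  invisible(written)
}

#' Conditional FDR Manhattan plot
#'
#' @param cfdr A `cfdr_result` table.
#' @param loci Optional `locus_table`; leads are outlined and labelled by
#'   nearest gene, coloured by driving phenotype.
#' @param threshold Significance threshold (enlarged points below it).
#' @export
plot_manhattan <- function(cfdr, loci = NULL,
                           threshold = attr(cfdr, "threshold") %||% 0.01) {
  ord <- order(chrom_order(cfdr$chrom), cfdr$pos)
  df <- cfdr[ord, , drop = FALSE]
  offsets <- c(0, cumsum(tapply(df$pos, factor(df$chrom,
               levels = unique(df$chrom)), max)))
  xpos <- df$pos + offsets[as.integer(factor(df$chrom,
                                             levels = unique(df$chrom)))]
  y <- -log10(df$min_cfdr)
  chr_col <- c("grey30", "grey60")[as.integer(factor(df$chrom,
              levels = unique(df$chrom))) %% 2 + 1]
  sig <- df$significant
  graphics::plot(xpos, y, pch = 16, cex = ifelse(sig, 1.2, 0.4),
                 col = chr_col, xaxt = "n", xlab = "chromosome",
                 ylab = expression(-log[10] ~ "conditional FDR"))
  graphics::abline(h = -log10(threshold), lty = 2, col = "red")
  if (!is.null(loci)) {
    traits <- unique(loci$driving_trait)
    pal <- stats::setNames(grDevices::hcl.colors(max(3, length(traits)),
                                                 "Dark 2")[seq_along(traits)],
                           traits)
    li <- match(loci$lead, df$rsid)
    graphics::points(xpos[li], y[li], pch = 21, cex = 1.5, lwd = 2,
                     bg = pal[loci$driving_trait], col = "black")
    if ("genes" %in% names(loci))
      graphics::text(xpos[li], y[li], labels = sub(",.*", "", loci$genes),
                     pos = 3, cex = 0.6, col = pal[loci$driving_trait])
  }
  invisible(NULL)
}

#' Heatmap of a 2-D conditional FDR lookup table
#'
#' @param lookup A `cfdr_lookup`.
#' @export
plot_lookup <- function(lookup) {
  L <- -log10(lookup$fdr)
  graphics::image(lookup$grid_p1, lookup$grid_p2, L,
                  col = grDevices::hcl.colors(64, "viridis"),
                  xlab = expression(-log[10](p[1])),
                  ylab = expression(-log[10](p[2])),
                  main = paste0("conditional FDR | ", lookup$trait))
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
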
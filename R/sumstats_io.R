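#' Default column mapping for summary-statistics tables
#'
#' GWAS summary-statistics files come in many dialects; the reader therefore
#' takes an explicit mapping from internal field names to file column names.
#' The defaults cover the common `SNP CHR BP P` layout with optional effect
#' direction (`DIR`), minor allele frequency (`MAF`) and genic/intergenic
#' annotation category (`CAT`) columns.
#'
#' @return Named list mapping internal field names (`rsid`, `chrom`, `pos`,
#'   `p`, `direction`, `maf`, `category`) to expected file column names.
#' @export
default_column_map <- function() {
  list(rsid = "SNP", chrom = "CHR", pos = "BP", p = "P",
       direction = "DIR", maf = "MAF", category = "CAT")
}

#' Minimum representable p-value
#'
#' p-values of 0 (or below this floor) are replaced by the floor so that
#' -log10 transforms stay finite.
#' @keywords internal
P_FLOOR <- 1e-300

parse_direction <- function(x) {
  out <- rep(NA_integer_, length(x))
  x <- trimws(as.character(x))
  out[x %in% c("+", "1", "+1")] <- 1L
  out[x %in% c("-", "-1")] <- -1L
  # numeric effect sizes: use their sign
  num <- suppressWarnings(as.numeric(x))
  miss <- is.na(out) & !is.na(num) & num != 0
  out[miss] <- ifelse(num[miss] > 0, 1L, -1L)
  out
}

normalize_category <- function(x) {
  x <- tolower(trimws(as.character(x)))
  x[!x %in% c("intergenic", "genic", "other")] <- "unknown"
  x
}

#' Read a GWAS summary-statistics table
#'
#' Reads a whitespace- or tab-separated file with a header row into a
#' validated table of variant records. Rows with missing or non-numeric
#' p-values (and p-values outside (0, 1]) are dropped with a message;
#' p-values of exactly 0 or below `p_floor` are floored at `p_floor` with a
#' warning, so that downstream -log10 transforms remain finite.
#'
#' @param path Path to the summary-statistics file.
#' @param column_map Named list mapping internal field names to file column
#'   names; see [default_column_map()]. `rsid` and `p` are mandatory.
#' @param p_floor Minimum positive p-value substituted for zeros/underflows.
#' @return A `data.frame` of class `"sumstats"` with columns `rsid`,
#'   `chrom`, `pos`, `p`, `direction` (-1, +1 or `NA` for unknown),
#'   `maf`, `category` (one of intergenic/genic/other/unknown). The number
#'   of dropped rows is recorded in attribute `n_dropped`.
#' @export
read_sumstats <- function(path, column_map = default_column_map(),
                          p_floor = P_FLOOR) {
  cm <- utils::modifyList(default_column_map(), as.list(column_map))
  raw <- utils::read.table(path, header = TRUE, sep = "",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character")
  for (field in c("rsid", "p")) {
    if (!cm[[field]] %in% names(raw)) {
      stop("summary-statistics file '", path, "' is missing mandatory column '",
           cm[[field]], "' (mapped field '", field, "')", call. = FALSE)
    }
  }
  col_or_na <- function(field, n) {
    if (!is.null(cm[[field]]) && cm[[field]] %in% names(raw)) raw[[cm[[field]]]]
    else rep(NA_character_, n)
  }
  n <- nrow(raw)
  out <- data.frame(
    rsid = as.character(raw[[cm$rsid]]),
    chrom = as.character(col_or_na("chrom", n)),
    pos = suppressWarnings(as.numeric(col_or_na("pos", n))),
    p = suppressWarnings(as.numeric(raw[[cm$p]])),
    direction = parse_direction(col_or_na("direction", n)),
    maf = suppressWarnings(as.numeric(col_or_na("maf", n))),
    category = normalize_category(col_or_na("category", n)),
    stringsAsFactors = FALSE
  )
  bad <- is.na(out$p) | out$p < 0 | out$p > 1
  if (any(bad)) {
    message("read_sumstats: dropped ", sum(bad),
            " row(s) with missing or invalid p-values from '", path, "'")
    out <- out[!bad, , drop = FALSE]
  }
  floored <- out$p < p_floor   # includes exact zeros
  if (any(floored)) {
    warning("read_sumstats: floored ", sum(floored),
            " p-value(s) below ", p_floor, call. = FALSE)
    out$p[floored] <- p_floor
  }
  dup <- duplicated(out$rsid)
  if (any(dup)) {
    stop("duplicate rsid in '", path, "': first duplicate is '",
         out$rsid[which(dup)[1]], "'", call. = FALSE)
  }
  rownames(out) <- NULL
  attr(out, "n_dropped") <- sum(bad)
  class(out) <- c("sumstats", "data.frame")
  out
}

#' Intersect a primary trait with conditioning traits into an aligned panel
#'
#' Restricts all traits to the SNPs present in every table, preserving the
#' primary table's SNP order, and aligns all p-value vectors to that order.
#' This is the joint (P1, P2) panel on which all conditional statistics are
#' computed.
#'
#' @param primary `sumstats` table of the primary trait.
#' @param conditioners Named list of `sumstats` tables for the conditioning
#'   traits (at least one).
#' @param primary_name Label for the primary trait.
#' @return An object of class `"aligned_panel"`: a list with `snps`
#'   (data.frame of rsid/chrom/pos/direction of the primary trait),
#'   `p_primary`, `p_cond` (named list of aligned p-value vectors),
#'   `trait_names` and `gc_applied` (named logical, all `FALSE` initially).
#' @export
intersect_traits <- function(primary, conditioners, primary_name = "primary") {
  if (!is.list(conditioners) || length(conditioners) < 1L)
    stop("at least one conditioning trait is required", call. = FALSE)
  if (is.null(names(conditioners)) || any(names(conditioners) == ""))
    names(conditioners) <- paste0("trait", seq_along(conditioners) + 1L)
  if (nrow(primary) == 0L || any(vapply(conditioners, nrow, 0L) == 0L))
    stop("all trait tables must be nonempty", call. = FALSE)
  common <- Reduce(intersect, lapply(conditioners, `[[`, "rsid"),
                   primary$rsid)
  if (length(common) == 0L)
    stop("empty SNP intersection across traits", call. = FALSE)
  keep <- primary$rsid %in% common
  snps <- primary[keep, c("rsid", "chrom", "pos", "direction"), drop = FALSE]
  rownames(snps) <- NULL
  p_cond <- lapply(conditioners, function(tab) {
    tab$p[match(snps$rsid, tab$rsid)]
  })
  message("intersect_traits: ", nrow(snps), " SNPs common to all ",
          length(conditioners) + 1L, " traits")
  gc_applied <- stats::setNames(rep(FALSE, length(conditioners) + 1L),
                                c(primary_name, names(conditioners)))
  structure(list(snps = snps,
                 p_primary = primary$p[keep],
                 p_cond = p_cond,
                 trait_names = c(primary_name, names(conditioners)),
                 gc_applied = gc_applied),
            class = "aligned_panel")
}

#' @export
print.aligned_panel <- function(x, ...) {
  cat("Aligned GWAS panel:", length(x$p_primary), "SNPs\n")
  cat("  primary trait:     ", x$trait_names[1], "\n")
  cat("  conditioning on:   ", paste(names(x$p_cond), collapse = ", "), "\n")
  cat("  GC applied:        ",
      paste(names(x$gc_applied)[x$gc_applied], collapse = ", "), "\n")
  invisible(x)
}

#' Write an aligned panel to a TSV file
#'
#' p-values are written as decimal text with 17 significant digits so that
#' re-reading reproduces them bit-exactly.
#'
#' @param panel An `aligned_panel`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  df <- data.frame(SNP = panel$snps$rsid, CHR = panel$snps$chrom,
                   BP = panel$snps$pos,
                   stringsAsFactors = FALSE)
  df[[paste0("P_", panel$trait_names[1])]] <- sprintf("%.17g", panel$p_primary)
  for (tr in names(panel$p_cond))
    df[[paste0("P_", tr)]] <- sprintf("%.17g", panel$p_cond[[tr]])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an aligned panel written by [write_panel()]
#'
#' @param path Path to a panel TSV.
#' @return An `aligned_panel` (GC flags reset to `FALSE`).
#' @export
read_panel <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  pcols <- grep("^P_", names(df), value = TRUE)
  if (length(pcols) < 2L)
    stop("panel file must contain at least two P_<trait> columns", call. = FALSE)
  traits <- sub("^P_", "", pcols)
  p_cond <- lapply(pcols[-1], function(cl) as.numeric(df[[cl]]))
  names(p_cond) <- traits[-1]
  structure(list(
    snps = data.frame(rsid = as.character(df$SNP), chrom = as.character(df$CHR),
                      pos = as.numeric(df$BP), direction = NA_integer_,
                      stringsAsFactors = FALSE),
    p_primary = as.numeric(df[[pcols[1]]]),
    p_cond = p_cond,
    trait_names = traits,
    gc_applied = stats::setNames(rep(FALSE, length(traits)), traits)),
    class = "aligned_panel")
}

# Shared TSV writer for result tables: tab-separated, no quoting, no rownames.
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
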
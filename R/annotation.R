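#' Read a BED-like gene table
#'
#' Columns: `CHROM START END SYMBOL [STRAND]`. Coordinates are interpreted
#' as 1-based inclusive; set `zero_based = TRUE` for true BED input
#' (0-based half-open), which is converted on read.
#'
#' @param path Path to the gene table.
#' @param zero_based Is the input 0-based half-open (BED convention)?
#' @return `data.frame` with columns `chrom`, `start`, `end`, `symbol`,
#'   `strand`.
#' @export
read_gene_table <- function(path, zero_based = FALSE) {
  df <- utils::read.table(path, header = TRUE, sep = "",
                          stringsAsFactors = FALSE)
  need <- c("CHROM", "START", "END", "SYMBOL")
  if (!all(need %in% names(df)))
    stop("gene table must have columns CHROM START END SYMBOL", call. = FALSE)
  out <- data.frame(chrom = as.character(df$CHROM),
                    start = as.numeric(df$START),
                    end = as.numeric(df$END),
                    symbol = as.character(df$SYMBOL),
                    strand = if ("STRAND" %in% names(df))
                      as.character(df$STRAND) else "unknown",
                    stringsAsFactors = FALSE)
  if (zero_based) out$start <- out$start + 1
  if (any(out$start > out$end)) stop("gene with start > end", call. = FALSE)
  if (any(out$symbol == "" | is.na(out$symbol)))
    stop("empty gene symbol", call. = FALSE)
  out
}

# distance of a position to a set of gene intervals: 0 inside the body,
# otherwise the gap to the nearest edge
gene_distances <- function(pos, genes) {
  d <- numeric(nrow(genes))
  left <- pos < genes$start
  right <- pos > genes$end
  d[left] <- genes$start[left] - pos
  d[right] <- pos - genes$end[right]
  d
}

#' Nearest gene of a SNP
#'
#' Distance is 0 when the SNP lies within the gene body, otherwise the gap
#' to the closest gene edge; strand is ignored. Ties are broken by
#' lexicographically smaller symbol (logged). With no gene on the SNP's
#' chromosome the annotation is `NA`, flagged by a warning.
#'
#' @param chrom,pos SNP coordinates (1-based).
#' @param genes Gene table from [read_gene_table()].
#' @return List with `symbol` and `distance` (bp); both `NA` when the
#'   chromosome carries no gene.
#' @export
nearest_gene <- function(chrom, pos, genes) {
  g <- genes[genes$chrom == chrom, , drop = FALSE]
  if (nrow(g) == 0L) {
    warning("no gene on chromosome ", chrom, ": annotation NA", call. = FALSE)
    return(list(symbol = NA_character_, distance = NA_real_))
  }
  d <- gene_distances(pos, g)
  dmin <- min(d)
  cand <- sort(g$symbol[d == dmin])
  if (length(cand) > 1L)
    message("nearest_gene: tie at distance ", dmin, " between ",
            paste(cand, collapse = ", "), "; keeping ", cand[1])
  list(symbol = cand[1], distance = dmin)
}

# gene set of one SNP: all genes covering it (distance 0), else the single
# nearest gene
snp_gene_set <- function(chrom, pos, genes) {
  g <- genes[genes$chrom == chrom, , drop = FALSE]
  if (nrow(g) == 0L) return(character(0))
  d <- gene_distances(pos, g)
  if (any(d == 0)) sort(unique(g$symbol[d == 0]))
  else sort(g$symbol[d == min(d)])[1]
}

#' Nearest-gene annotation for a SNP table
#'
#' @param snps `data.frame` with columns `rsid`, `chrom`, `pos`.
#' @param genes Gene table.
#' @return `snps` with added `gene` and `gene_distance` columns.
#' @export
annotate_snps <- function(snps, genes) {
  ann <- lapply(seq_len(nrow(snps)),
                function(i) nearest_gene(snps$chrom[i], snps$pos[i], genes))
  snps$gene <- vapply(ann, `[[`, "", "symbol")
  snps$gene_distance <- vapply(ann, `[[`, 0, "distance")
  snps
}

#' Annotate loci with gene sets and locus class
#'
#' The gene set of a locus is the union of its members' nearest genes;
#' members falling inside overlapping gene bodies contribute every covering
#' gene. A locus is `complex` when its gene set has more than one symbol,
#' otherwise `single-gene`.
#'
#' @param loci A `locus_table` from [assign_blocks()].
#' @param snps SNP table with `rsid`, `chrom`, `pos` covering all members.
#' @param genes Gene table.
#' @return `loci` with added `genes` (comma-separated symbols) and
#'   `loc_class` columns.
#' @export
annotate_loci <- function(loci, snps, genes) {
  mem <- locus_member_list(loci)
  gsets <- lapply(mem, function(members) {
    idx <- match(members, snps$rsid)
    if (anyNA(idx)) stop("locus member(s) missing from SNP table", call. = FALSE)
    sort(unique(unlist(lapply(idx, function(i)
      snp_gene_set(snps$chrom[i], snps$pos[i], genes)))))
  })
  loci$genes <- vapply(gsets, paste, "", collapse = ",")
  loci$loc_class <- ifelse(vapply(gsets, length, 0L) > 1L,
                           "complex", "single-gene")
  loci
}
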
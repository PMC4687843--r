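#' Read pairwise LD r-squared triplets
#'
#' Reads a precomputed LD file (tab/whitespace-separated, header
#' `SNP_A SNP_B R2`) from a reference panel. Each unordered pair is stored
#' once; duplicated pairs keep the maximum r2 (logged). SNP pairs absent
#' from the file are treated as unlinked (r2 = 0) downstream.
#'
#' @param path Path to the LD triplet file.
#' @return `data.frame` with columns `rsid_a`, `rsid_b`, `r2`.
#' @export
read_ld_triplets <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "",
                          stringsAsFactors = FALSE)
  need <- c("SNP_A", "SNP_B", "R2")
  if (!all(need %in% names(df)))
    stop("LD file must have columns SNP_A SNP_B R2", call. = FALSE)
  out <- data.frame(rsid_a = as.character(df$SNP_A),
                    rsid_b = as.character(df$SNP_B),
                    r2 = as.numeric(df$R2), stringsAsFactors = FALSE)
  if (any(is.na(out$r2)) || any(out$r2 < 0) || any(out$r2 > 1))
    stop("LD r2 values must lie in [0, 1]", call. = FALSE)
  # canonical unordered orientation, keep max r2 per pair
  flip <- out$rsid_a > out$rsid_b
  tmp <- out$rsid_a[flip]; out$rsid_a[flip] <- out$rsid_b[flip]
  out$rsid_b[flip] <- tmp
  key <- paste(out$rsid_a, out$rsid_b, sep = "\r")
  if (anyDuplicated(key)) {
    message("read_ld_triplets: collapsing ", sum(duplicated(key)),
            " duplicated pair(s), keeping max r2")
    out <- out[order(key, -out$r2), , drop = FALSE]
    out <- out[!duplicated(paste(out$rsid_a, out$rsid_b, sep = "\r")), ,
               drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

# Reject LD edges joining SNPs on different chromosomes; LD is
# intra-chromosomal. `chrom_of` is a named chromosome vector by rsid.
check_ld_intra_chrom <- function(edges, chrom_of) {
  ca <- chrom_of[edges$rsid_a]; cb <- chrom_of[edges$rsid_b]
  known <- !is.na(ca) & !is.na(cb)
  bad <- known & ca != cb
  if (any(bad))
    stop("inter-chromosomal LD edge(s), e.g. ",
         edges$rsid_a[which(bad)[1]], "-", edges$rsid_b[which(bad)[1]],
         call. = FALSE)
  invisible(TRUE)
}

# adjacency list of edges above the r2 cut, restricted to the given rsids
ld_adjacency <- function(edges, rsids, r2_cut) {
  keep <- edges$r2 > r2_cut & edges$rsid_a %in% rsids & edges$rsid_b %in% rsids
  e <- edges[keep, , drop = FALSE]
  adj <- stats::setNames(vector("list", length(rsids)), rsids)
  if (nrow(e) > 0L) {
    for (i in seq_len(nrow(e))) {
      a <- e$rsid_a[i]; b <- e$rsid_b[i]; r <- e$r2[i]
      adj[[a]] <- c(adj[[a]], stats::setNames(r, b))
      adj[[b]] <- c(adj[[b]], stats::setNames(r, a))
    }
  }
  adj
}

#' Greedy lead-SNP selection among significant SNPs
#'
#' Ranks significant SNPs by increasing conditional FDR and walks the list,
#' keeping a SNP as a lead unless it is in LD (r2 strictly greater than
#' `r2_cut`) with a previously kept lead. Ties in cFDR are broken by
#' smaller nominal p-value, then lexicographic rsid. SNPs absent from the
#' LD file are treated as unlinked.
#'
#' @param sig_snps `data.frame` with columns `rsid`, `cfdr` and optionally
#'   `p` (nominal p-value, used for tie-breaking).
#' @param edges LD triplets from [read_ld_triplets()].
#' @param r2_cut LD pruning threshold (default 0.2; the rule is strictly
#'   `r2 > r2_cut`).
#' @return Character vector of lead rsids in selection (cFDR) order.
#' @export
greedy_lead_selection <- function(sig_snps, edges, r2_cut = 0.2) {
  stopifnot(all(c("rsid", "cfdr") %in% names(sig_snps)))
  p <- if ("p" %in% names(sig_snps)) sig_snps$p else rep(0, nrow(sig_snps))
  ord <- order(sig_snps$cfdr, p, sig_snps$rsid)
  rsids <- sig_snps$rsid[ord]
  adj <- ld_adjacency(edges, rsids, r2_cut)
  in_ld_file <- unique(c(edges$rsid_a, edges$rsid_b))
  n_unlinked <- sum(!rsids %in% in_ld_file)
  if (n_unlinked > 0L)
    message("greedy_lead_selection: ", n_unlinked,
            " significant SNP(s) absent from the LD file, treated as unlinked")
  removed <- stats::setNames(rep(FALSE, length(rsids)), rsids)
  leads <- character(0)
  for (snp in rsids) {
    if (removed[[snp]]) next
    leads <- c(leads, snp)
    nb <- names(adj[[snp]])
    if (length(nb) > 0L) removed[nb] <- TRUE
  }
  leads
}

#' Cluster significant SNPs into LD blocks around the leads
#'
#' Every non-lead significant SNP is assigned to the lead with which it has
#' maximal r2 above the cut. Loci are numbered by genomic order of their
#' lead SNP (chromosome, then position).
#'
#' @param leads Lead rsids from [greedy_lead_selection()].
#' @param sig_snps `data.frame` with columns `rsid`, `cfdr`, and (for
#'   genomic ordering and the locus table) `chrom`, `pos`, and optionally
#'   `driving_trait`.
#' @param edges LD triplets.
#' @param r2_cut LD threshold (must match the lead selection).
#' @return `data.frame` of class `"locus_table"`, one row per locus:
#'   `locus_id`, `lead`, `chrom`, `pos` (lead position), `members`
#'   (comma-separated rsids), `n_members`, `min_cfdr`, `driving_trait`.
#' @export
assign_blocks <- function(leads, sig_snps, edges, r2_cut = 0.2) {
  stopifnot(all(leads %in% sig_snps$rsid))
  chrom_of <- NULL
  if ("chrom" %in% names(sig_snps)) {
    chrom_of <- stats::setNames(sig_snps$chrom, sig_snps$rsid)
    check_ld_intra_chrom(edges, chrom_of)
  }
  adj <- ld_adjacency(edges, sig_snps$rsid, r2_cut)
  assignment <- stats::setNames(rep(NA_character_, nrow(sig_snps)),
                                sig_snps$rsid)
  assignment[leads] <- leads
  for (snp in setdiff(sig_snps$rsid, leads)) {
    nb <- adj[[snp]]
    cand <- nb[names(nb) %in% leads]
    if (length(cand) == 0L) {
      # unreachable when leads come from greedy selection on the same edges
      assignment[[snp]] <- snp
      leads <- c(leads, snp)
      next
    }
    assignment[[snp]] <- names(cand)[which.max(cand)]
  }
  cfdr_of <- stats::setNames(sig_snps$cfdr, sig_snps$rsid)
  drv <- if ("driving_trait" %in% names(sig_snps))
    stats::setNames(sig_snps$driving_trait, sig_snps$rsid) else NULL
  loci <- lapply(unique(assignment[leads]), function(ld) {
    members <- sort(names(assignment)[assignment == ld])
    mc <- min(cfdr_of[members])
    best <- members[which.min(cfdr_of[members])]
    data.frame(lead = ld,
               chrom = if (!is.null(chrom_of)) chrom_of[[ld]] else NA_character_,
               pos = if ("pos" %in% names(sig_snps))
                 sig_snps$pos[match(ld, sig_snps$rsid)] else NA_real_,
               members = paste(members, collapse = ","),
               n_members = length(members),
               min_cfdr = mc,
               driving_trait = if (!is.null(drv)) drv[[best]] else NA_character_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, loci)
  chrom_rank <- chrom_order(out$chrom)
  out <- out[order(chrom_rank, out$pos, out$lead), , drop = FALSE]
  out$locus_id <- seq_len(nrow(out))
  rownames(out) <- NULL
  out <- out[, c("locus_id", setdiff(names(out), "locus_id"))]
  class(out) <- c("locus_table", "data.frame")
  out
}

# numeric ordering of chromosome labels; X sorts after 22
chrom_order <- function(chrom) {
  num <- suppressWarnings(as.numeric(chrom))
  num[toupper(chrom) == "X"] <- 23
  num[is.na(num)] <- 99
  num
}

locus_member_list <- function(loci) strsplit(loci$members, ",", fixed = TRUE)

locus_gene_list <- function(loci) {
  if (!"genes" %in% names(loci)) stop("loci are not annotated with genes",
                                      call. = FALSE)
  lapply(strsplit(loci$genes, ",", fixed = TRUE),
         function(g) g[g != "" & g != "NA"])
}

#' Overlap report between two locus tables
#'
#' Two loci are overlapping when their member rsid sets intersect or their
#' gene-symbol sets intersect. Also returns the number of distinct loci in
#' the union of both tables (overlapping loci merged by connected
#' components).
#'
#' @param loci_a,loci_b Annotated `locus_table`s (with a `genes` column).
#' @return List with `pairs` (data.frame of overlapping locus id pairs and
#'   what they share) and `n_union` (distinct locus count).
#' @export
overlap_loci <- function(loci_a, loci_b) {
  mem_a <- locus_member_list(loci_a); mem_b <- locus_member_list(loci_b)
  gen_a <- locus_gene_list(loci_a);  gen_b <- locus_gene_list(loci_b)
  pairs <- list()
  # union-find over the nA + nB loci
  parent <- seq_len(nrow(loci_a) + nrow(loci_b))
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(nrow(loci_a))) {
    for (j in seq_len(nrow(loci_b))) {
      shared_snps <- intersect(mem_a[[i]], mem_b[[j]])
      shared_genes <- intersect(gen_a[[i]], gen_b[[j]])
      if (length(shared_snps) > 0L || length(shared_genes) > 0L) {
        pairs[[length(pairs) + 1L]] <- data.frame(
          locus_a = loci_a$locus_id[i], locus_b = loci_b$locus_id[j],
          shared_rsids = paste(shared_snps, collapse = ","),
          shared_genes = paste(shared_genes, collapse = ","),
          stringsAsFactors = FALSE)
        ri <- find(i); rj <- find(nrow(loci_a) + j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  roots <- vapply(seq_along(parent), find, 0L)
  list(pairs = if (length(pairs)) do.call(rbind, pairs) else
         data.frame(locus_a = integer(0), locus_b = integer(0),
                    shared_rsids = character(0), shared_genes = character(0)),
       n_union = length(unique(roots)))
}

#' Classify loci as novel or replication against a known-locus list
#'
#' A locus replicates a prior finding when it contains a known rsid or a
#' known ("close-by") gene; otherwise it is novel. The gene side of the
#' rule is operationalized as the locus's annotated nearest-gene set
#' intersecting the known gene list.
#'
#' @param loci Annotated `locus_table` (with a `genes` column).
#' @param known_rsids Character vector of rsids from the primary study
#'   (may be empty).
#' @param known_genes Character vector of gene symbols from the primary
#'   study (may be empty).
#' @return `loci` with an added `novelty` column
#'   (`"novel"` / `"replication"`).
#' @export
novelty_filter <- function(loci, known_rsids = character(0),
                           known_genes = character(0)) {
  mem <- locus_member_list(loci)
  gen <- locus_gene_list(loci)
  rep_call <- vapply(seq_len(nrow(loci)), function(i) {
    length(intersect(mem[[i]], known_rsids)) > 0L ||
      length(intersect(gen[[i]], known_genes)) > 0L
  }, TRUE)
  loci$novelty <- ifelse(rep_call, "replication", "novel")
  loci
}

#' Read a known-locus list
#'
#' @param path TSV with columns `RSID` and `GENE` (either may be `NA` on a
#'   given row).
#' @return List with `rsids` and `genes` character vectors.
#' @export
read_known_loci <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "",
                          stringsAsFactors = FALSE)
  if (!all(c("RSID", "GENE") %in% names(df)))
    stop("known-locus file must have columns RSID and GENE", call. = FALSE)
  list(rsids = unique(stats::na.omit(as.character(df$RSID))),
       genes = unique(stats::na.omit(as.character(df$GENE))))
}
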
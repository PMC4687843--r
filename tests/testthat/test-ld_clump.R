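edges_df <- function(a, b, r2) data.frame(rsid_a = a, rsid_b = b, r2 = r2,
                                          stringsAsFactors = FALSE)

test_that("greedy selection keeps the best SNP and prunes its LD partners", {
  sig <- data.frame(rsid = c("rsA", "rsB", "rsC"),
                    cfdr = c(1e-4, 1e-3, 5e-3), stringsAsFactors = FALSE)
  edges <- edges_df(c("rsA", "rsB"), c("rsB", "rsC"), c(0.5, 0.1))
  leads <- suppressMessages(greedy_lead_selection(sig, edges))
  expect_equal(leads, c("rsA", "rsC"))   # B pruned by A; C survives (r2 0.1)

  # no edges: every significant SNP is a lead
  leads2 <- suppressMessages(greedy_lead_selection(sig, edges_df(
    character(0), character(0), numeric(0))))
  expect_equal(leads2, c("rsA", "rsB", "rsC"))

  # boundary: r2 == 0.2 exactly is NOT pruned (rule is strictly > 0.2)
  leads3 <- suppressMessages(greedy_lead_selection(
    sig, edges_df("rsA", "rsB", 0.2)))
  expect_true("rsB" %in% leads3)

  # the first lead is always the globally minimal-cFDR SNP
  expect_equal(leads[1], sig$rsid[which.min(sig$cfdr)])
})

test_that("block assignment follows maximal r2 and numbers loci genomically", {
  sig <- data.frame(rsid = c("rsA", "rsB", "rsC"),
                    cfdr = c(1e-4, 1e-3, 5e-3),
                    chrom = c("2", "2", "1"), pos = c(100, 200, 50),
                    stringsAsFactors = FALSE)
  edges <- edges_df("rsA", "rsB", 0.5)
  leads <- suppressMessages(greedy_lead_selection(sig, edges))
  loci <- assign_blocks(leads, sig, edges)
  expect_s3_class(loci, "locus_table")
  expect_equal(loci$members, c("rsC", "rsA,rsB"))   # chrom 1 locus first
  expect_equal(loci$locus_id, 1:2)
  expect_equal(loci$min_cfdr, c(5e-3, 1e-4))

  # single significant SNP -> one singleton locus
  one <- data.frame(rsid = "rsZ", cfdr = 1e-3, chrom = "1", pos = 1,
                    stringsAsFactors = FALSE)
  l1 <- assign_blocks("rsZ", one, edges_df(character(0), character(0),
                                           numeric(0)))
  expect_equal(nrow(l1), 1L)
  expect_equal(l1$n_members, 1L)

  # a SNP linked to two leads joins the one with larger r2
  sig2 <- data.frame(rsid = c("rsL1", "rsL2", "rsX"),
                     cfdr = c(1e-5, 2e-5, 1e-3),
                     chrom = "1", pos = c(100, 5000, 2000),
                     stringsAsFactors = FALSE)
  edges2 <- edges_df(c("rsL1", "rsL2"), c("rsX", "rsX"), c(0.3, 0.6))
  leads2 <- suppressMessages(greedy_lead_selection(sig2, edges2))
  expect_equal(sort(leads2), c("rsL1", "rsL2"))
  loci2 <- assign_blocks(leads2, sig2, edges2)
  expect_true(grepl("rsX", loci2$members[loci2$lead == "rsL2"]))
})

test_that("inter-chromosomal LD edges are rejected", {
  sig <- data.frame(rsid = c("rsA", "rsB"), cfdr = c(1e-4, 1e-3),
                    chrom = c("1", "2"), pos = c(1, 2),
                    stringsAsFactors = FALSE)
  expect_error(assign_blocks("rsA", sig, edges_df("rsA", "rsB", 0.5)),
               "inter-chromosomal")
})

test_that("leads are pairwise unlinked and loci partition the significant SNPs", {
  for (s in 1:5) {
    set.seed(s)
    n <- 40
    sig <- data.frame(rsid = sprintf("rs%02d", 1:n), cfdr = runif(n, 0, 0.01),
                      chrom = as.character(sample(1:2, n, TRUE)),
                      pos = sample(1e6, n), stringsAsFactors = FALSE)
    # random LD edges within chromosomes
    cmb <- t(combn(n, 2))
    same <- sig$chrom[cmb[, 1]] == sig$chrom[cmb[, 2]]
    keep <- same
    keep[same] <- runif(sum(same)) < 0.15
    cmb <- cmb[keep, , drop = FALSE]
    edges <- edges_df(sig$rsid[cmb[, 1]], sig$rsid[cmb[, 2]],
                      runif(nrow(cmb)))
    leads <- suppressMessages(greedy_lead_selection(sig, edges, 0.2))
    # exhaustive pairwise check against the edge list
    high <- edges[edges$r2 > 0.2, ]
    for (i in seq_len(nrow(high)))
      expect_false(high$rsid_a[i] %in% leads && high$rsid_b[i] %in% leads)
    loci <- assign_blocks(leads, sig, edges, 0.2)
    members <- unlist(strsplit(loci$members, ","))
    expect_setequal(members, sig$rsid)        # every SNP in exactly one locus
    expect_equal(anyDuplicated(members), 0L)
    expect_equal(nrow(loci), length(leads))
    # determinism: identical inputs give identical tables
    leads_b <- suppressMessages(greedy_lead_selection(sig, edges, 0.2))
    expect_identical(assign_blocks(leads_b, sig, edges, 0.2), loci)
  }
})

test_that("LD triplet reading validates, canonicalizes and deduplicates pairs", {
  path <- tempfile()
  writeLines(c("SNP_A\tSNP_B\tR2", "rs2\trs1\t0.5", "rs1\trs2\t0.3",
               "rs3\trs4\t0.1"), path)
  edges <- suppressMessages(read_ld_triplets(path))
  expect_equal(nrow(edges), 2L)
  expect_equal(edges$r2[edges$rsid_a == "rs1"], 0.5)   # max kept, canonical order
  bad <- tempfile(); writeLines(c("SNP_A\tSNP_B\tR2", "rs1\trs2\t1.5"), bad)
  expect_error(read_ld_triplets(bad), "0, 1")
})

test_that("locus overlap uses shared rsids or shared genes and counts the union", {
  mk_loci <- function(ids, members, genes) {
    df <- data.frame(locus_id = ids, lead = vapply(strsplit(members, ","),
                                                   `[`, "", 1),
                     members = members, genes = genes,
                     stringsAsFactors = FALSE)
    class(df) <- c("locus_table", "data.frame"); df
  }
  a <- mk_loci(1:3, c("rs1,rs2", "rs3", "rs4"), c("G1", "G2", "G3"))
  b <- mk_loci(1:2, c("rs2", "rs9"), c("G9", "G8"))
  ov <- overlap_loci(a, b)              # shared rsid rs2
  expect_equal(nrow(ov$pairs), 1L)
  expect_equal(ov$pairs$shared_rsids, "rs2")
  expect_equal(ov$n_union, 4L)          # 3 + 2 - 1 overlapping pair

  b2 <- mk_loci(1, "rs99", "G2")        # disjoint rsids, shared gene symbol
  ov2 <- overlap_loci(a, b2)
  expect_equal(ov2$pairs$shared_genes, "G2")
  expect_equal(ov2$n_union, 3L)

  b3 <- mk_loci(1, "rs99", "G99")       # fully disjoint
  expect_equal(overlap_loci(a, b3)$n_union, 4L)
})

test_that("novelty classification matches the known-locus rule", {
  mk <- function(n, genes) {
    df <- data.frame(locus_id = seq_len(n), lead = sprintf("rs%d", seq_len(n)),
                     members = sprintf("rs%d", seq_len(n)), genes = genes,
                     stringsAsFactors = FALSE)
    class(df) <- c("locus_table", "data.frame"); df
  }
  loci <- mk(10, sprintf("G%d", 1:10))
  # empty known lists: everything is novel
  all_novel <- novelty_filter(loci)
  expect_true(all(all_novel$novelty == "novel"))
  # known rsid -> replication
  byrs <- novelty_filter(loci, known_rsids = "rs3")
  expect_equal(byrs$novelty[3], "replication")
  expect_equal(sum(byrs$novelty == "novel"), 9L)
  # 4 loci hit known genes only -> 6 novel
  bygene <- novelty_filter(loci, known_genes = c("G1", "G4", "G7", "G9"))
  expect_equal(sum(bygene$novelty == "novel"), 6L)
})
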
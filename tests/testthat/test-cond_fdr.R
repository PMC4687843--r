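# toy panel used by the hand-counted examples
toy <- make_panel(c(0.01, 0.2, 0.5, 0.9), list(t2 = c(0.001, 0.5, 0.02, 0.9)))

test_that("conditional CDF matches exhaustive hand counts on the toy panel", {
  # slice P2 <= 0.02 = {snp1, snp3}; of those P1 <= 0.2 = {snp1}
  expect_equal(conditional_cdf(0.2, 0.02, toy), 0.5)
  # p1 = 1 is certain within any nonempty slice
  expect_equal(conditional_cdf(1, 0.001, toy), 1)
  expect_equal(conditional_cdf(1, 0.9, toy), 1)
  # p2 = 1 degenerates to the full-panel ECDF
  expect_equal(conditional_cdf(0.2, 1, toy), 0.5)
  expect_equal(conditional_cdf(0.9, 1, toy), 1)
  # empty slice is flagged undefined
  expect_true(is.na(conditional_cdf(0.5, 1e-6, toy)))
})

test_that("pointwise cFDR is p1 over the conditional CDF, clipped at 1", {
  expect_equal(cfdr_point(0.2, 0.02, toy), 0.4)
  # empty slice -> maximally conservative 1
  expect_equal(cfdr_point(0.2, 1e-6, toy), 1)
  # clipping: p1/F > 1 returns exactly 1 (0.85 / 0.75 would exceed 1)
  expect_identical(cfdr_point(0.85, 1, toy), 1)
})

test_that("unconditional FDR is the p2 = 1 degenerate case", {
  expect_equal(uncond_fdr(0.2, toy), 0.4)   # 2 of 4 P1 <= 0.2
  expect_equal(uncond_fdr(c(0.01, 0.2), toy),
               cfdr_point(c(0.01, 0.2), c(1, 1), toy))
  # uniform null panel: FDR ~ 1 everywhere
  set.seed(5)
  nullp <- make_panel(runif(5000), list(t2 = runif(5000)))
  q <- c(0.01, 0.1, 0.5)
  expect_true(all(uncond_fdr(q, nullp) > 0.8))
})

test_that("cfdr_point and conditional_cdf match a brute-force double-loop oracle", {
  set.seed(101)
  n <- 800
  panel <- make_panel(c(runif(n - 50), 10^-runif(50, 2, 8)),
                      list(t2 = c(runif(n - 50), 10^-runif(50, 1, 6))))
  P1 <- panel$p_primary; P2 <- panel$p_cond$t2
  q1 <- c(runif(250), 10^-runif(250, 0, 7))
  q2 <- c(runif(250), 10^-runif(250, 0, 5))
  for (k in sample(500, 500)) {
    denom <- 0L; num <- 0L
    for (i in seq_len(n)) {            # independent counting oracle
      if (P2[i] <= q2[k]) {
        denom <- denom + 1L
        if (P1[i] <= q1[k]) num <- num + 1L
      }
    }
    expected_cdf <- if (denom == 0L) NA_real_ else num / denom
    expect_identical(conditional_cdf(q1[k], q2[k], panel), expected_cdf)
    expected_cfdr <- if (denom == 0L || num == 0L) 1
                     else min(1, q1[k] / (num / denom))
    expect_identical(cfdr_point(q1[k], q2[k], panel), expected_cfdr)
  }
})

test_that("lookup nodes reproduce independent pointwise recomputation exactly", {
  set.seed(21)
  panel <- make_panel(c(runif(400), 10^-runif(100, 1, 8)),
                      list(t2 = c(runif(400), 10^-runif(100, 1, 6))))
  g1 <- seq(0, 8, by = 0.5); g2 <- seq(0, 6, by = 1)
  lk <- build_lookup(panel, "t2", g1, g2)
  for (a in seq_along(g1))
    for (b in seq_along(g2))
      expect_identical(lk$fdr[a, b],
                       cfdr_point(10^-g1[a], 10^-g2[b], panel),
                       label = sprintf("node (%g, %g)", g1[a], g2[b]))
  # node at (0, 0), p1 = p2 = 1 -> 1/1 = 1
  expect_identical(lk$fdr[1, 1], 1)
  # values live in (0, 1]
  expect_true(all(lk$fdr > 0 & lk$fdr <= 1))
})

test_that("the single-row p2 = 1 lookup reproduces the unconditional FDR curve", {
  set.seed(22)
  panel <- make_panel(runif(1000), list(t2 = runif(1000)))
  g1 <- seq(0, 6, by = 0.25)
  lk <- build_lookup(panel, "t2", g1, grid_p2 = c(0, 10))
  expect_equal(lk$fdr[, 1], uncond_fdr(10^-g1, panel))
})

test_that("monotonization applies a running minimum along the p1 axis", {
  set.seed(23)
  panel <- make_panel(c(runif(300), 1e-4, 2e-4), list(t2 = runif(302)))
  lk <- build_lookup(panel, "t2", seq(0, 6, 0.2), c(0, 1, 2),
                     monotonize = TRUE)
  for (b in 1:3) expect_true(all(diff(lk$fdr[, b]) <= 0))
})

test_that("bilinear interpolation is exact at nodes, averages at midpoints, clamps outside", {
  set.seed(31)
  panel <- make_panel(c(runif(500), 10^-runif(100, 0, 9)),
                      list(t2 = c(runif(500), 10^-runif(100, 0, 9))))
  lk <- build_lookup(panel, "t2")
  # exactness at randomly chosen nodes
  ii <- sample(length(lk$grid_p1), 20); jj <- sample(length(lk$grid_p2), 20)
  for (k in 1:20)
    expect_equal(interpolate_fdr(lk, 10^-lk$grid_p1[ii[k]],
                                 10^-lk$grid_p2[jj[k]]),
                 lk$fdr[ii[k], jj[k]], tolerance = 1e-12)
  # closed-form midpoint of four nodes with -log10 values (1, 1, 3, 3) -> 2
  hand <- structure(list(grid_p1 = c(0, 1), grid_p2 = c(0, 1),
                         fdr = matrix(c(1e-1, 1e-1, 1e-3, 1e-3), 2, 2),
                         n_at_node = c(10L, 10L), trait = "t2",
                         monotonized = FALSE), class = "cfdr_lookup")
  expect_equal(interpolate_fdr(hand, 10^-0.5, 10^-0.5), 1e-2)
  # clamping beyond the grid hits the boundary node
  expect_equal(interpolate_fdr(lk, 1e-12, 1),
               lk$fdr[length(lk$grid_p1), 1])
})

test_that("interpolated assignments stay close to pointwise values on a refined grid", {
  set.seed(32)
  panel <- make_panel(c(runif(2000), 10^-runif(500, 0, 9)),
                      list(t2 = c(runif(2000), 10^-runif(500, 0, 9))))
  coarse <- build_lookup(panel, "t2")
  q1 <- 10^-runif(1000, 0, 10); q2 <- 10^-runif(1000, 0, 10)
  approx_v <- interpolate_fdr(coarse, q1, q2)
  exact_v <- cfdr_point(q1, q2, panel)
  # grid-induced bound: interpolation error within the max -log10 jump
  # observed between nodes of a 10x refined grid
  fine <- build_lookup(panel, "t2", seq(0, 10, 0.01), seq(0, 10, 0.05))
  Lf <- -log10(fine$fdr)
  bound <- max(abs(diff(Lf)), abs(t(diff(t(Lf))))) * 11
  expect_lt(max(abs(log10(approx_v) - log10(exact_v))), bound)
})

test_that("summaries pick the minimum across traits and its driving phenotype", {
  set.seed(41)
  panel <- make_panel(c(1e-5, 1e-3, 0.4, runif(200)),
                      list(a = c(1e-4, 0.5, 0.6, runif(200)),
                           b = c(0.2, 1e-4, 0.7, runif(200))))
  lks <- list(a = build_lookup(panel, "a"), b = build_lookup(panel, "b"))
  res <- cfdr_summarize(panel, lks, threshold = 0.01)
  expect_equal(res$min_cfdr, pmin(res$cfdr_a, res$cfdr_b))
  expect_equal(res$driving_trait,
               ifelse(res$cfdr_a <= res$cfdr_b, "a", "b"))  # ties -> config order
  expect_equal(res$significant, res$min_cfdr < 0.01)

  # single conditioning trait: min equals that trait, driving trait is it
  res1 <- cfdr_summarize(panel, lks["a"])
  expect_equal(res1$min_cfdr, res1$cfdr_a)
  expect_true(all(res1$driving_trait == "a"))

  # trait mismatch is an error
  expect_error(cfdr_summarize(panel, list(zzz = lks$a)), "not in panel")
})

test_that("significance is a strict comparison against the threshold", {
  hand <- structure(list(grid_p1 = c(0, 10), grid_p2 = c(0, 10),
                         fdr = matrix(0.01, 2, 2), n_at_node = c(1L, 1L),
                         trait = "t2", monotonized = FALSE),
                    class = "cfdr_lookup")
  panel <- make_panel(c(0.5, 0.5), list(t2 = c(0.5, 0.5)))
  res <- cfdr_summarize(panel, list(t2 = hand), threshold = 0.01)
  expect_false(any(res$significant))   # cfdr == threshold is not significant
})

test_that("conditioning improves power over the unconditional FDR under pleiotropy", {
  wins <- vapply(1:10, function(s) {
    dat <- sim_two_trait_panel(sim_config(n_snps = 20000, seed = s))
    lk <- build_lookup(dat$panel, "trait2")
    cf <- interpolate_fdr(lk, dat$panel$p_primary, dat$panel$p_cond$trait2)
    uf <- uncond_fdr(dat$panel$p_primary, dat$panel)
    true_pos <- dat$label %in% c("t1", "pleio")
    sum(cf < 0.01 & true_pos) >= sum(uf < 0.01 & true_pos)
  }, TRUE)
  expect_gte(mean(wins), 0.9)
})
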
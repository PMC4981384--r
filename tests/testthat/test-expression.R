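make_ct <- function(ct_map) {
  # ct_map: list gene -> list(fraction -> vector of per-bio Ct means)
  rows <- list()
  for (g in names(ct_map)) for (f in names(ct_map[[g]])) {
    v <- ct_map[[g]][[f]]
    for (b in seq_along(v))
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g, fraction = f, bio_rep = paste0("b", b),
        tech_rep = "t1", ct = v[b], stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

test_that("standard curves recover efficiency from the slope", {
  d <- data.frame(log10_dilution = 0:-4, ct = 18 + 3.3219 * (0:4))
  sc <- fit_standard_curve(d)
  expect_equal(sc$efficiency, 2, tolerance = 1e-4)
  expect_equal(sc$r2, 1, tolerance = 1e-9)

  d2 <- data.frame(log10_dilution = 0:-4, ct = 20 + 3.6 * (0:4))
  expect_equal(fit_standard_curve(d2)$efficiency, 10^(1 / 3.6),
               tolerance = 1e-6)

  expect_error(fit_standard_curve(d[1:2, ]), "at least 3")
})

test_that("efficiency-adjusted relative expression follows the closed form", {
  ct <- make_ct(list(t = list(f1 = c(20, 20, 20)),
                     r = list(f1 = c(20, 20, 20))))
  e <- list(t = 2, r = 2)
  expect_equal(relative_expression_method1(ct, "t", "r", e)$rel_expr, 1)

  ct2 <- make_ct(list(t = list(f1 = c(21, 21, 21)),
                      r = list(f1 = c(20, 20, 20))))
  expect_equal(relative_expression_method1(ct2, "t", "r", e)$rel_expr, 0.5)

  ct3 <- make_ct(list(t = list(f1 = 20), r = list(f2 = 20)))
  expect_error(relative_expression_method1(ct3, "t", "r", e), "missing")
})

test_that("Pfaffl ratios follow the closed form and reduce to 2^ddCt at E=2", {
  e <- list(t = 2, r = 2)
  ct <- make_ct(list(t = list(ctrl = c(24, 24), smp = c(21, 21)),
                     r = list(ctrl = c(20, 20), smp = c(19, 19))))
  pf <- pfaffl_ratio(ct, "t", "r", e, "ctrl", "smp")
  expect_equal(pf$ratio, 4)  # 2^3 / 2^1

  # identity with the classic 2^-ddCt at perfect doubling
  ddct <- (21 - 24) - (19 - 20)
  expect_equal(pf$ratio, 2^(-ddct))

  ct0 <- make_ct(list(t = list(ctrl = c(20, 20), smp = c(20, 20)),
                      r = list(ctrl = c(20, 20), smp = c(20, 20))))
  expect_equal(pfaffl_ratio(ct0, "t", "r", e, "ctrl", "smp")$ratio, 1)
})

test_that("Pfaffl equals the ratio of within-fraction relative expressions", {
  set.seed(14)
  for (k in 1:20) {
    e <- list(t = runif(1, 1.7, 2.1), r = runif(1, 1.7, 2.1))
    ct <- make_ct(list(
      t = list(ctrl = runif(3, 18, 30), smp = runif(3, 18, 30)),
      r = list(ctrl = runif(3, 18, 30), smp = runif(3, 18, 30))))
    m1 <- relative_expression_method1(ct, "t", "r", e)
    pf <- pfaffl_ratio(ct, "t", "r", e, "ctrl", "smp")
    # identity holds per biological replicate, hence for single-rep means;
    # check it replicate-wise
    per_rep <- function(f) {
      tt <- ct[ct$gene == "t" & ct$fraction == f, ]
      rr <- ct[ct$gene == "r" & ct$fraction == f, ]
      e$t^(-tt$ct) / e$r^(-rr$ct)
    }
    expect_equal(pf$ratio, mean(per_rep("smp") / per_rep("ctrl")),
                 tolerance = 1e-9)
  }
})

test_that("housekeeping screening ranks the most stable candidate first", {
  ct <- make_ct(list(stable = list(f1 = c(20, 20), f2 = c(20, 20)),
                     drift = list(f1 = c(20, 20), f2 = c(26, 26))))
  hk <- housekeeping_stability(ct, c("drift", "stable"))
  expect_equal(hk$gene[1], "stable")
  expect_equal(hk$cv[1], 0)

  single <- make_ct(list(a = list(f1 = 20), b = list(f1 = 21)))
  expect_error(housekeeping_stability(single, c("a", "b")), "two fractions")
})

test_that("a planted stable housekeeping gene wins the screen across seeds", {
  genes <- data.frame(gene = c("hk", "d1", "d2"),
                      efficiency = c(2, 2, 2))
  folds <- rbind(c(1, 1, 1), c(1, 4, 0.5), c(1, 0.25, 2))
  wins <- 0L
  for (s in 1:100) {
    q <- generate_qpcr(genes, folds, noise_sd = 0.15, seed = s)
    hk <- housekeeping_stability(q$ct, genes$gene)
    wins <- wins + (hk$gene[1] == "hk")
  }
  expect_gte(wins / 100, 0.99)
})

test_that("group tests reproduce classical t and F statistics", {
  gt <- group_tests(list(a = c(1, 2, 3), b = c(4, 5, 6)))
  expect_equal(gt$statistic, -3.674235, tolerance = 1e-6)
  expect_equal(gt$p_value, 0.0213, tolerance = 1e-3)
  expect_equal(gt$df, 4)

  same <- group_tests(list(a = c(2, 2), b = c(2, 2)))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  f0 <- group_tests(list(a = c(1, 2), b = c(1, 2), c = c(1, 2)))
  expect_equal(f0$method, "anova")
  expect_equal(f0$statistic, 0)

  expect_error(group_tests(list(a = 1, b = c(1, 2))), "two replicates")
  expect_error(group_tests(list(a = c(1, 1), b = c(2, 2))), "degenerate")
})

test_that("planted fold changes are recovered within 15% under realistic noise", {
  genes <- data.frame(gene = c("tgt", "ref"), efficiency = c(1.95, 2.0))
  folds <- rbind(c(1, 8, 1), c(1, 1, 1))
  ratios <- vapply(1:100, function(s) {
    q <- generate_qpcr(genes, folds, noise_sd = 0.15, seed = s)
    curves <- lapply(q$dilution_series, fit_standard_curve)
    pfaffl_ratio(q$ct, "tgt", "ref", curves, "total", "calcifying")$ratio
  }, numeric(1))
  expect_lt(abs(mean(ratios) - 8) / 8, 0.15)

  # noiseless generation recovers the fold exactly with known efficiencies
  q0 <- generate_qpcr(genes, folds, noise_sd = 0, seed = 1)
  pf0 <- pfaffl_ratio(q0$ct, "tgt", "ref",
                      list(tgt = 1.95, ref = 2), "total", "calcifying")
  expect_equal(pf0$ratio, 8, tolerance = 1e-9)
})
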
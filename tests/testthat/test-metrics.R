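test_that("the four metrics match their definitions on crafted cases", {
  b <- ball_mask(5, 17)
  expect_equal(dsc(b, b), 1.0)
  expect_equal(rve(b, b), 0.0)
  expect_equal(hausdorff(b, b), 0.0)
  expect_equal(assd(b, b), 0.0)
  # disjoint masks: DSC 0
  g1 <- array(FALSE, c(12, 6, 6)); g1[2, 3, 3] <- TRUE
  g2 <- array(FALSE, c(12, 6, 6)); g2[9, 3, 3] <- TRUE
  m1 <- binary_mask(g1); m2 <- binary_mask(g2)
  expect_equal(dsc(m1, m2), 0.0)
  # |R| = 4, |P| = 4, overlap 2 -> 0.5
  ga <- array(FALSE, c(8, 8, 1)); ga[1:4, 1, 1] <- TRUE
  gb <- array(FALSE, c(8, 8, 1)); gb[3:6, 1, 1] <- TRUE
  expect_equal(dsc(binary_mask(ga), binary_mask(gb)), 0.5)
  # RVE arithmetic and sign contract
  gr <- array(FALSE, c(10, 10, 10)); gr[1:100] <- TRUE
  gp <- array(FALSE, c(10, 10, 10)); gp[1:110] <- TRUE
  expect_equal(rve(binary_mask(gr), binary_mask(gp)), 0.10)
  sub <- binary_mask(array(gr & c(rep(TRUE, 50), rep(FALSE, 950)), dim(gr)))
  expect_lt(rve(binary_mask(gr), sub), 0)
  # two unit voxels 7 apart at 1 mm -> HD 7; ASSD averages both directions
  expect_equal(hausdorff(m1, m2), 7.0)
  expect_equal(assd(m1, m2), 7.0)
  expect_equal(hausdorff(m1, m2), hausdorff(m2, m1))
  # 5 mm apart via spacing
  m5 <- binary_mask(g1, spacing = c(5 / 7, 1, 1))
  m5b <- binary_mask(g2, spacing = c(5 / 7, 1, 1))
  expect_equal(assd(m5, m5b), 5.0)
  # degenerate conventions
  e <- binary_mask(array(FALSE, c(4, 4, 4)))
  expect_equal(as.numeric(dsc(e, e)), 1.0)
  expect_true(attr(dsc(e, e), "degenerate"))
  expect_error(rve(e, b), class = "ms_geometry_error")
  expect_error(hausdorff(binary_mask(array(FALSE, dim(b$grid))), b),
               class = "ms_empty_mask_error")
})

test_that("metrics agree with the brute-force oracle on random masks", {
  for (seed in 1:12) {
    ref <- random_mask(seed, n = 16)
    pred <- random_mask(seed + 100, n = 16)
    if (!any(ref$grid) || !any(pred$grid)) next
    o <- oracle_metrics(ref, pred)
    expect_lt(abs(dsc(ref, pred) - o$dsc), 1e-9)
    expect_lt(abs(rve(ref, pred) - o$rve), 1e-9)
    expect_lt(abs(hausdorff(ref, pred) - o$hd), 1e-9)
    expect_lt(abs(assd(ref, pred) - o$assd), 1e-9)
    expect_lte(assd(ref, pred), hausdorff(ref, pred))
  }
})

test_that("metrics are translation-invariant and spacing-covariant", {
  ref <- random_mask(3, n = 14)
  pred <- random_mask(77, n = 14)
  shift <- function(m) {
    g <- array(FALSE, dim(m$grid) + 4L)
    g[3:(dim(m$grid)[1] + 2), 3:(dim(m$grid)[2] + 2), 3:(dim(m$grid)[3] + 2)] <-
      m$grid
    binary_mask(g, m$spacing)
  }
  expect_equal(dsc(shift(ref), shift(pred)), dsc(ref, pred))
  expect_equal(hausdorff(shift(ref), shift(pred)), hausdorff(ref, pred))
  expect_equal(assd(shift(ref), shift(pred)), assd(ref, pred))
  # scaling the spacing scales the distances and leaves DSC alone
  s2 <- function(m) binary_mask(m$grid, m$spacing * 2)
  expect_equal(dsc(s2(ref), s2(pred)), dsc(ref, pred))
  expect_equal(hausdorff(s2(ref), s2(pred)), 2 * hausdorff(ref, pred))
  expect_equal(assd(s2(ref), s2(pred)), 2 * assd(ref, pred))
})

test_that("pooled reports merge labels and omit the pooled HD", {
  sp <- phantom_spec(n_subjects = 1, labels = 2, shape = c(48, 48, 24),
                     base_radius = 5, variability = 0, seed = 0)
  gt <- generate_multilabel_phantom(sp)
  rep0 <- pooled_metrics(gt, gt)
  expect_true(all(rep0$dsc == 1))
  expect_true(all(rep0$assd == 0))
  expect_true(is.na(rep0$hd[rep0$label == "pooled"]))
  # one label perfect, the other empty in pred: pooled DSC strictly between
  pred <- gt
  pred$grid[pred$grid == 2L] <- 0L
  expect_warning(rep1 <- pooled_metrics(gt, pred), NA)
  d1 <- rep1$dsc[rep1$label == "1"]
  d2 <- rep1$dsc[rep1$label == "2"]
  dp <- rep1$dsc[rep1$label == "pooled"]
  expect_true(dp > min(d1, d2) && dp < max(d1, d2))
  # label order does not change the report rows
  expect_identical(pooled_metrics(gt, pred, labels = c(2, 1)),
                   pooled_metrics(gt, pred, labels = c(1, 2)))
})

test_that("signed-rank p-values are exact for small n and symmetric", {
  # all-positive differences with distinct magnitudes, n = 5
  w <- wilcoxon_signed_rank(c(5, 6, 7, 8, 9), c(1, 2, 3, 3.5, 4))
  expect_equal(w$p.value, 0.0625)
  expect_equal(w$statistic, 15)
  # full enumeration oracle on random paired data, n = 6..10
  set.seed(42)
  for (n in c(6, 8, 10)) {
    a <- rnorm(n)
    b <- a + rnorm(n)
    expect_lt(abs(wilcoxon_signed_rank(a, b)$p.value -
                    oracle_signed_rank_p(a, b)), 1e-12)
  }
  # cross-check against the base R implementation (no ties, exact mode)
  set.seed(9)
  a <- rnorm(10); b <- a + rnorm(10)
  expect_equal(wilcoxon_signed_rank(a, b)$p.value,
               wilcox.test(a, b, paired = TRUE, exact = TRUE)$p.value)
  # two-sided symmetry and degenerate input
  expect_equal(wilcoxon_signed_rank(a, b)$p.value,
               wilcoxon_signed_rank(b, a)$p.value)
  expect_error(wilcoxon_signed_rank(a, a),
               class = "ms_degenerate_sample_error")
  # large-n normal approximation stays close to the exact base R value
  set.seed(10)
  a2 <- rnorm(30); b2 <- a2 + rnorm(30, 0.4)
  expect_lt(abs(wilcoxon_signed_rank(a2, b2)$p.value -
                  wilcox.test(a2, b2, paired = TRUE, exact = FALSE,
                              correct = TRUE)$p.value), 1e-6)
})
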
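mk_vol <- function(values, nx = NULL) {
  if (is.null(nx)) nx <- length(values)
  ct_volume(array(values, c(nx, 1, 1)), c(1, 1, 1), kind = "dose")
}
mk_mask <- function(flags, ref) structure_mask(array(flags, dim(ref$data)),
                                               ref, "m")

test_that("difference statistics use the population convention", {
  a <- mk_vol(c(1, 2, 3)); b <- mk_vol(c(0, 0, 0))
  region <- mk_mask(c(TRUE, TRUE, TRUE), a)
  s <- diff_stats(a, b, region)
  expect_equal(s$mean, 2)
  expect_equal(s$std, sqrt(2 / 3))   # population (divide by n)
  expect_equal(c(s$min, s$max, s$n), c(1, 3, 3))
  expect_equal(diff_stats(a, a, region)$std, 0)
  # masking contract: region excluding the differing voxels gives zeros
  r2 <- mk_mask(c(FALSE, FALSE, TRUE), a)
  b2 <- mk_vol(c(9, 9, 0))
  expect_equal(diff_stats(a, b2, r2)$mean, 3)
  expect_error(diff_stats(a, mk_vol(c(1, 2)), region), "mismatch")
  expect_error(diff_stats(a, b, mk_mask(c(FALSE, FALSE, FALSE), a)), "empty")
})

test_that("cumulative DVH and D_x match their definitions and a brute-force oracle", {
  u <- mk_vol(rep(10, 5))
  m <- mk_mask(rep(TRUE, 5), u)
  dvh <- cumulative_dvh(u, m)
  expect_equal(dose_at_volume(dvh, 95), 10, tolerance = 0.051)
  expect_equal(dose_at_volume(dvh, 100), 10)
  two <- mk_vol(c(8, 12))
  m2 <- mk_mask(c(TRUE, TRUE), two)
  dvh2 <- cumulative_dvh(two, m2)
  i10 <- which.min(abs(dvh2$dose - 10))
  expect_equal(dvh2$volume[i10], 0.5)
  expect_equal(dose_at_volume(dvh2, 100), 8)
  expect_true(all(diff(dvh2$volume) <= 0))
  expect_equal(dvh2$volume[1], 1)
  expect_error(dose_at_volume(dvh2, 0), "in")
  # brute-force sort oracle on random volumes: agreement within one bin
  set.seed(4)
  for (rep in 1:5) {
    nvox <- sample(100:10000, 1)
    dv <- mk_vol(runif(nvox, 0, 12))
    mm <- mk_mask(rep(TRUE, nvox), dv)
    dd <- cumulative_dvh(dv, mm, bin_gy = 0.05)
    vals <- sort(dv$data, decreasing = TRUE)
    for (x in c(95, 98, 100)) {
      oracle <- vals[max(1, floor(x / 100 * nvox))]
      expect_lt(abs(dose_at_volume(dd, x) - oracle), 0.051)
    }
    expect_true(all(dose_at_volume(dd, 100) <= dose_at_volume(dd, 98) + 1e-12))
    expect_true(all(dose_at_volume(dd, 98) <= dose_at_volume(dd, 95) + 1e-12))
  }
})

test_that("the relative accuracy error follows its formula and is scale invariant", {
  expect_equal(accuracy_error(10, 10), 0)
  expect_equal(accuracy_error(9.5, 10), 5.0)
  expect_equal(accuracy_error(12.356, 10), 23.56, tolerance = 1e-10)
  for (k in c(0.1, 2, 50))
    expect_equal(accuracy_error(k * 9.3, k * 10), accuracy_error(9.3, 10))
  expect_error(accuracy_error(5, 0), "positive")
})

test_that("the rank-sum test matches full enumeration in the exact regime", {
  r <- rank_sum_test(c(1, 2), c(3, 4))
  expect_equal(unname(r$U), 0)
  expect_equal(r$p, 1 / 3, tolerance = 1e-12)
  expect_equal(r$method, "exact")
  same <- rank_sum_test(c(5, 7, 9), c(5, 7, 9))
  expect_equal(unname(same$U), 9 / 2)   # n m / 2 under exchangeability
  set.seed(11)
  for (rep in 1:8) {
    n <- sample(2:6, 1); m <- sample(2:6, 1)
    x <- sample(seq(1, 400, by = 7), n)
    y <- sample(seq(3, 401, by = 7), m)
    r <- rank_sum_test(x, y)
    expect_equal(r$method, "exact")
    expect_equal(r$p, enumerate_ranksum_p(x, y), tolerance = 1e-9)
  }
  # exact and normal approximation agree for n = m = 8
  set.seed(12)
  x <- sample(seq(1, 1000, 11), 8); y <- sample(seq(5, 1004, 11), 8)
  p_exact <- rank_sum_test(x, y)$p
  w <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                           correct = TRUE))
  expect_lt(abs(p_exact - w$p.value), 0.02)
})

test_that("dose-difference maps are antisymmetric with correct extremes", {
  a <- mk_vol(c(1, 5, 2)); b <- mk_vol(c(2, 1, 2))
  d1 <- dose_difference_map(a, b)
  d2 <- dose_difference_map(b, a)
  expect_equal(d1$map$data, -d2$map$data)
  expect_equal(c(d1$min, d1$max), c(-1, 4))
  expect_true(all(dose_difference_map(a, a)$map$data == 0))
  expect_error(dose_difference_map(a, mk_vol(1:2)), "mismatch")
})

test_that("the study report has the full metric structure and zero error on identical inputs", {
  base <- ct_volume(array(runif(64, 0, 5) + 5, c(4, 4, 4)), c(1, 1, 1))
  body <- mk_mask(rep(TRUE, 64), base)
  ptv <- mk_mask(rep(c(TRUE, FALSE), 32), base)
  ds <- list(uncorrected = base, corrected = base, gt = base, body = body)
  mkplan <- function() list(ptv = ptv, plan = NULL, fluence = NULL,
                            doses = list(uncorrected = base,
                                         corrected = base, gt = base))
  plans <- list(lowZ = list(PTV1 = mkplan(), PTV2 = mkplan(),
                            PTV3 = mkplan()),
                highZ = list(PTV1 = mkplan(), PTV2 = mkplan(),
                             PTV3 = mkplan()))
  rep <- evaluate_study(list(lowZ = ds, highZ = ds), plans)
  tab <- report_acc_table(rep)
  expect_equal(nrow(tab), 36)   # 2 configs x 3 PTVs x 2 datasets x 3 metrics
  expect_true(all(tab$acc_percent == 0))
  expect_error(evaluate_study(list(lowZ = ds[1:2]), plans),
               "missing artifact")
})
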
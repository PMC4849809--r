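test_that("SMR summary methods follow their definitions", {
  v <- c(10, 8, 12, 9, 11)
  expect_equal(estimate_smr(v, "lowest")$value, 8)
  expect_equal(estimate_smr(v, "mean_lowest_n", 2)$value, 8.5)
  expect_equal(estimate_smr(v, "quantile", 0.5)$value, 10)
  expect_error(estimate_smr(v, "mean_lowest_n", 9), "N")
  expect_error(estimate_smr(v, "quantile", 1.5), "p in")
  expect_error(estimate_smr(v[1:4], "lowest"), ">= 5")
})

test_that("a low quantile of noisy routine MO2 approaches the true SMR", {
  set.seed(11)
  mo2 <- 100 * rlnorm(200, 0, 0.04)
  est <- estimate_smr(mo2, "quantile", 0.15)
  expect_lt(abs(est$value - 100) / 100, 0.05)
})

test_that("zero-speed extrapolation inverts an exact exponential", {
  speed <- seq(0.5, 3, by = 0.5)
  mo2 <- 80 * exp(0.4 * speed)
  est <- estimate_smr(mo2, "zero_speed_extrapolation", speed = speed)
  expect_equal(est$value, 80, tolerance = 1e-10)
  expect_error(estimate_smr(c(-1, mo2), "zero_speed_extrapolation",
                            speed = c(0, speed)), "non-positive")
})

test_that("broken-stick recovers a constructed breakpoint exactly", {
  po2 <- seq(20, 1, length.out = 20)
  mo2 <- ifelse(po2 >= 5, 100, 20 * po2)
  res <- pcrit_broken_stick(data.frame(po2 = po2, mo2 = mo2))
  expect_equal(res$pcrit, 5.0)
  expect_equal(res$classification, "oxyregulator")
  expect_equal(res$rss_two_segment, 0, tolerance = 1e-18)
  expect_lte(res$rss_two_segment, res$rss_one_segment)
  expect_equal(unname(res$segment_below[["slope"]]), 20, tolerance = 1e-8)
  expect_equal(unname(res$segment_above[["slope"]]), 0, tolerance = 1e-8)
})

test_that("proportional data classify as an obligate oxyconformer", {
  po2 <- seq(18, 1.5, length.out = 15)
  res <- pcrit_broken_stick(data.frame(po2 = po2, mo2 = 10 * po2))
  expect_equal(res$classification, "oxyconformer")
  expect_true(is.na(res$pcrit))
})

test_that("broken-stick recovers a simulated Pcrit of 5.15 kPa", {
  s <- simulate_mo2_series(fish_profile("regulator", rmr = 100,
                                        pcrit = 5.15),
                           seq(21, 1, length.out = 30), noise_sd = 0.05,
                           seed = 7)
  res <- pcrit_broken_stick(s)
  expect_equal(res$classification, "oxyregulator")
  expect_lt(abs(res$pcrit - 5.15), 0.5)
  ci <- pcrit_broken_stick(s, n_boot = 200, seed = 1)$confidence_interval
  expect_true(ci[1] <= res$pcrit && res$pcrit <= ci[2])
})

test_that("broken-stick matches a brute-force breakpoint-grid oracle", {
  set.seed(99)
  n_ok <- 0
  for (i in 1:50) {
    bp <- runif(1, 3, 9)
    po2 <- sort(runif(14, 0.5, 20), decreasing = TRUE)
    true <- ifelse(po2 >= bp, 100, 100 * po2 / bp)
    mo2 <- true * (1 + rnorm(14, 0, 0.04))
    got <- tryCatch(pcrit_broken_stick(data.frame(po2 = po2, mo2 = mo2)),
                    error = function(e) NULL)
    if (is.null(got) || got$classification != "oxyregulator") next
    orc <- oracle_breakpoint(po2, mo2)
    # the estimator searches observed points and midpoints; the fine-grid
    # oracle may land anywhere inside the same inter-point interval, so
    # agreement is to the local candidate resolution
    gaps <- diff(sort(po2))
    res_tol <- max(gaps) / 2 + diff(range(po2)) / 2000
    expect_lt(abs(got$pcrit - orc$breakpoint), res_tol + 1e-9)
    # both searches should find essentially the same optimum
    expect_lt(abs(orc$rss - got$rss_two_segment),
              0.02 * max(orc$rss, 1e-9))
    n_ok <- n_ok + 1
  }
  expect_gte(n_ok, 40)
})

test_that("shifting all MO2 by a constant leaves the breakpoint unchanged", {
  s <- simulate_mo2_series(fish_profile("regulator", rmr = 100, pcrit = 6),
                           seq(20, 1, length.out = 25), noise_sd = 0.05,
                           seed = 5)
  base <- pcrit_broken_stick(s)
  shifted <- pcrit_broken_stick(data.frame(po2 = s$po2, mo2 = s$mo2 + 37))
  expect_equal(shifted$pcrit, base$pcrit)
})

test_that("intersection of the conforming line with SMR gives Pcrit", {
  po2 <- seq(20, 1, length.out = 20)
  mo2 <- ifelse(po2 >= 5, 100, 20 * po2)
  res <- pcrit_intersection(data.frame(po2 = po2, mo2 = mo2), 100)
  expect_equal(res$pcrit, 5.0, tolerance = 1e-8)
  deg <- pcrit_intersection(data.frame(po2 = po2, mo2 = mo2), 0)
  expect_equal(deg$pcrit, 0, tolerance = 1e-8)
  expect_true(deg$degenerate)
  s <- simulate_mo2_series(fish_profile("regulator", rmr = 100,
                                        pcrit = 5.15),
                           seq(21, 1, length.out = 30), noise_sd = 0.05,
                           seed = 7)
  smr <- estimate_smr(s$mo2[s$po2 > 10], "quantile", 0.5)
  est <- pcrit_intersection(s, smr)
  expect_lt(abs(est$pcrit - 5.15), 0.7)
  # declining "conforming" data have no upward line to intersect
  down <- data.frame(po2 = po2, mo2 = 200 - 5 * po2)
  expect_error(pcrit_intersection(down, 100), "slope")
})

test_that("nonlinear saturating fit recovers exact Michaelis-Menten data", {
  po2 <- seq(20, 0.5, length.out = 15)
  mo2 <- 100 * po2 / (1 + po2)
  res <- pcrit_nonlinear(data.frame(po2 = po2, mo2 = mo2))
  expect_equal(res$K, 1, tolerance = 1e-6)
  expect_equal(res$mo2max, 100, tolerance = 1e-6)
  expect_equal(res$pcrit, 9.0, tolerance = 1e-5)   # 0.9/(1-0.9) * K
  expect_equal(res$fraction, 0.9)
  res2 <- pcrit_nonlinear(data.frame(po2 = po2, mo2 = mo2), fraction = 0.5)
  expect_equal(res2$pcrit, 1.0, tolerance = 1e-5)
})

test_that("the asymptote-fraction Pcrit sits above the breakpoint on
          regulator data", {
  # a saturating curve approaches its plateau gradually, so the PO2 at 90%
  # of the asymptote lies above the abrupt breakpoint of the same data --
  # the documented, definitional bias of the nonlinear operationalization
  s <- simulate_mo2_series(fish_profile("regulator", rmr = 100, pcrit = 5),
                           seq(21, 1, length.out = 30), noise_sd = 0.05,
                           seed = 12)
  bs <- pcrit_broken_stick(s)
  nl <- pcrit_nonlinear(s)
  expect_gt(nl$pcrit, bs$pcrit)
  expect_false(nl$degenerate)
  # a less demanding fraction reads off a lower threshold
  expect_lt(pcrit_nonlinear(s, fraction = 0.5)$pcrit, nl$pcrit)
})

test_that("flat saturated data are flagged as a degenerate K -> 0 edge", {
  po2 <- seq(20, 1, length.out = 12)
  res <- pcrit_nonlinear(data.frame(po2 = po2, mo2 = rep(100, 12)))
  expect_true(res$degenerate)
})

test_that("series preconditions are enforced", {
  expect_error(pcrit_broken_stick(data.frame(po2 = 1:5, mo2 = 1:5)),
               ">= 8")
  expect_error(pcrit_broken_stick(data.frame(po2 = seq(10, 11, length.out = 9),
                                             mo2 = rnorm(9, 100))),
               "4-fold")
})
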
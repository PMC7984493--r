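test_that("D_X% matches the brute-force cumulative-histogram oracle", {
  # two equal voxels: at least 50% of the volume receives >= 80
  expect_equal(dose_at_volume(c(60, 80), 50), 80)
  expect_lte(abs(oracle_dose_at_volume(c(60, 80), 50) - 80), 0.011)
  # uniform dose: every D_X% equals it
  expect_equal(dose_at_volume(rep(7000, 100), c(1, 95, 99)), rep(7000, 3))
  set.seed(7)
  for (rep in 1:20) {
    n <- sample(10:1000, 1)
    d <- stats::runif(n, 0, 120)
    for (x in c(1, 5, 50, 95, 99)) {
      expect_lte(abs(dose_at_volume(d, x) - oracle_dose_at_volume(d, x)),
                 0.011)
    }
  }
})

test_that("D_X% is shift-equivariant and monotone in volume", {
  set.seed(21)
  d <- stats::runif(200, 6000, 7400)
  xs <- c(1, 2, 5, 50, 95, 99, 100)
  expect_equal(dose_at_volume(d + 13.5, xs), dose_at_volume(d, xs) + 13.5)
  expect_true(all(diff(dose_at_volume(d, xs)) <= 0))
  expect_equal(dose_at_volume(d, 100), min(d))
  expect_error(dose_at_volume(numeric(0), 95), "empty")
  expect_error(dose_at_volume(d, 0), "volume_pct")
})

test_that("homogeneity index is D99/D1 and scale-invariant", {
  expect_equal(homogeneity_index(rep(42, 50)), 1.0)
  # constructed array with known order statistics
  d <- c(rep(6790, 99), 7000)
  expect_equal(homogeneity_index(d), 6790 / 7000)
  set.seed(3)
  r <- stats::runif(300, 6500, 7300)
  expect_equal(homogeneity_index(2 * r), homogeneity_index(r))
  expect_error(homogeneity_index(rep(0, 10)), "D1")
})

test_that("WCS picks the least favorable scenario per metric kind", {
  v <- c(6900, 6850, 6950, 6910, 6880, 6890, 6920, 6860, 6930, 6940)
  expect_equal(wcs_select(v, "coverage"), 6850)
  expect_equal(wcs_select(v, "hotspot"), 6950)
  expect_equal(wcs_select(rep(0.97, 10), "hi"), 0.97)
  expect_error(wcs_select(v[1:9], "coverage"), "exactly 10")
  expect_equal(wcs_select(v[1:9], "coverage", strict = FALSE), 6850)
})

test_that("metric set reproduces the defining arithmetic of each metric", {
  # scenarios identical to nominal: all deltas and bandwidths vanish
  set.seed(11)
  nom <- stats::runif(400, 6800, 7150)
  same <- matrix(rep(nom, 10), ncol = 10)
  ms0 <- compute_metric_set(nom, same)
  expect_equal(ms0$delta_d1_pct, 0)
  expect_equal(ms0$delta_hi, 0)
  expect_equal(ms0$delta_davg_pct, 0)
  expect_equal(ms0$bw_avg_coverage_cgy, 0)
  expect_equal(ms0$bw_avg_highdose_cgy, 0)

  # hand-checkable construction: uniform scenario doses
  # nominal uniform 7200 except a D1 spike; WCS D1 = 7308 -> dD1 = 1.5%
  n <- 100
  nominal <- rep(7200, n)
  scen <- vapply(1:10, function(s) rep(7200, n), numeric(n))
  scen[, 4] <- rep(7308, n)
  ms <- compute_metric_set(nominal, scen)
  expect_equal(ms$delta_d1_pct, (7308 - 7200) / 7200 * 100)  # 1.5

  # coverage delta normalized by the prescription, not the nominal
  nominal2 <- rep(6950, n)
  scen2 <- vapply(1:10, function(s) rep(6950, n), numeric(n))
  scen2[, 7] <- rep(6880, n)
  ms2 <- compute_metric_set(nominal2, scen2, d_rx = 7000)
  expect_equal(ms2$delta_davg_pct, (6950 - 6880) / 7000 * 100)  # 1.0
  # the two normalizations are genuinely different denominators
  expect_equal(ms2$delta_d1_pct, (6950 - 6950) / 6950 * 100)
  # bandwidth: max - min across scenarios at each D_X%
  expect_equal(ms2$bw_avg_coverage_cgy, 70)
  expect_equal(ms2$bw_avg_highdose_cgy, 70)

  expect_error(compute_metric_set(nominal, scen[, 1:9]), "exactly 10")
  expect_error(compute_metric_set(nominal[1:50], scen), "voxel count")
})

test_that("hot-spot and coverage denominators are pinned separately", {
  # identical geometry, one hot scenario and one cold scenario
  n <- 200
  nominal <- rep(7000, n)
  scen <- matrix(7000, n, 10)
  scen[, 2] <- 7140   # hot: D1 WCS
  scen[, 9] <- 6790   # cold: coverage WCS
  ms <- compute_metric_set(nominal, scen, d_rx = 7000)
  expect_equal(ms$delta_d1_pct, (7140 - 7000) / 7000 * 100)   # nominal D1 denom
  expect_equal(ms$delta_davg_pct, (7000 - 6790) / 7000 * 100) # D_Rx denom
  # with a different nominal D1 the denominators diverge
  nominal2 <- c(rep(7000, n - 3), rep(7100, 3))
  ms2 <- compute_metric_set(nominal2, scen, d_rx = 7000)
  expect_equal(ms2$delta_d1_pct, (7140 - 7100) / 7100 * 100)
})

test_that("mean DVH is the pointwise scenario average", {
  n <- 50
  two <- cbind(rep(6000, n), rep(8000, n))
  md <- mean_dvh(two, grid = c(0, 5000, 7000, 9000))
  expect_equal(md$volume_fraction, c(1, 1, 0.5, 0))
  # identical scenarios: mean equals any one
  same <- cbind(rep(7000, n), rep(7000, n))
  md2 <- mean_dvh(same, grid = c(6999, 7000, 7001))
  expect_equal(md2$volume_fraction, c(1, 1, 0))
  # mean D_X% lies within the scenario envelope
  set.seed(5)
  scen <- vapply(1:10, function(s) stats::runif(300, 6500, 7300), numeric(300))
  md3 <- mean_dvh(scen)
  d95 <- apply(scen, 2, dose_at_volume, 95)
  # dose where the mean curve crosses 95%
  cross <- max(md3$dose_cgy[md3$volume_fraction >= 0.95])
  expect_gte(cross, min(d95) - 2)
  expect_lte(cross, max(d95) + 2)
  expect_error(mean_dvh(list(stats::runif(10), stats::runif(11))), "equal")
})
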
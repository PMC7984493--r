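test_that("SFUD plan covers the CTV depth extent with descending layers", {
  ph <- small_phantom()
  plan <- small_plan()
  b <- bragg_model()
  for (bm in plan$beams$beam) {
    sp <- plan$spots[plan$spots$beam == bm, ]
    layer_e <- sp %>%
      dplyr::distinct(.data$layer, .data$energy_mev) %>%
      dplyr::arrange(.data$layer)
    expect_true(all(diff(layer_e$energy_mev) < 0))
    # layer ranges bracket the brute-force CTV WEPL extent
    geom <- beam_geometry(ph, plan$beams$gantry_deg[plan$beams$beam == bm])
    ranges_mm <- range_from_energy(layer_e$energy_mev, b) * 10
    expect_gte(max(ranges_mm), max(geom$wepl_mm))
    expect_lte(min(ranges_mm), min(geom$wepl_mm))
  }
  # every spot deliverable
  expect_true(all(plan$spots$mu >= machine_model()$min_spot_mu * (1 - 1e-9)))
})

test_that("plan layer and spot counts sit in the plausible clinical band", {
  # ~30 cc CTV: expect 13-28 layers and 598-2150 spots per beam at the
  # default planning surrogates
  ph <- fixture("plan_band_phantom", function() {
    generate_phantom(phantom_config(ctv_volume_cc = 30, spacing_mm = 3))
  })
  plan <- fixture("plan_band_plan", function() generate_sfud_plan(ph, 2))
  st <- plan_statistics(plan)
  expect_true(all(st$n_layers >= 13 & st$n_layers <= 28))
  expect_true(all(st$n_spots >= 598 & st$n_spots <= 2150))
})

test_that("nonnegative least-squares weights solve decoupled systems exactly", {
  # single spot, single voxel: scalar inversion
  expect_equal(nnls_weights(matrix(2), 5), 2.5)
  # two non-overlapping spots, two voxels: diagonal system
  A <- diag(c(2, 4))
  expect_equal(nnls_weights(A, c(6, 6)), c(3, 1.5))
  # 50-spot toy case: objective never exceeds the uniform-weight baseline
  set.seed(42)
  A50 <- matrix(stats::runif(200 * 50), 200, 50)
  d <- rep(10, 200)
  w <- nnls_weights(A50, d, iterations = 50)
  obj <- function(w) sum((A50 %*% w - d)^2)
  c_unif <- sum(rowSums(A50) * d) / sum(rowSums(A50)^2)
  expect_lte(obj(w), obj(rep(c_unif, 50)))
  expect_true(all(w >= 0))
})

test_that("each SFUD field alone is nearly uniform over the CTV", {
  unif <- plan_uniformity(small_plan(), small_phantom())
  expect_true(all(unif$cv < planning_config()$uniformity_cv_max))
})

test_that("normalization pins D99 at the coverage level and is idempotent", {
  ph <- small_phantom()
  plan <- small_plan()
  nom <- static_dose(plan, ph)
  expect_equal(dose_at_volume(nom$dose_cgy, 99), 6930, tolerance = 1e-9)
  # scale invariance: halving all MU then renormalizing restores the plan
  halved <- plan
  halved$spots$mu <- plan$spots$mu / 2
  renorm <- normalize_plan(halved, ph)
  expect_equal(renorm$spots$mu, plan$spots$mu, tolerance = 1e-9)
  # idempotence
  again <- normalize_plan(plan, ph)
  expect_equal(again$spots$mu, plan$spots$mu, tolerance = 1e-12)
  # D99 already at target -> unit scale
  expect_equal(dose_at_volume(static_dose(again, ph)$dose_cgy, 99), 6930,
               tolerance = 1e-6)
})

test_that("plan statistics count layers, spots and MU consistently", {
  plan <- toy_plan(c(120, 100, 80), spots_per_layer = 10, mu = 0.1)
  st <- plan_statistics(plan)
  expect_equal(st$n_layers, 3)
  expect_equal(st$n_spots, 30)
  expect_equal(st$total_mu, 3)
  # VR5 repaint: 15 delivered layers
  st5 <- plan_statistics(build_vrx_plan(plan, 5))
  expect_equal(st5$n_layers, 15)
  # empty plan is an error, not a zero row
  empty <- plan
  empty$spots <- plan$spots[0, ]
  expect_error(plan_statistics(empty), "empty")
})

test_that("plans with non-descending layer energies are rejected", {
  spots <- tibble::tibble(beam = 1L, layer = 1:2, energy_mev = c(80, 120),
                          x_mm = 0, y_mm = 0, mu = 0.1)
  expect_error(pbs_plan(spots, tibble::tibble(beam = 1L, gantry_deg = 0)),
               "descending")
})

test_that("plan JSON and CSV round-trips are lossless", {
  plan <- small_plan()
  dir <- withr::local_tempdir()
  jp <- file.path(dir, "plan.json")
  write_plan_json(plan, jp)
  back <- read_plan_json(jp)
  expect_identical(back$spots$mu, plan$spots$mu)
  expect_identical(back$spots$x_mm, plan$spots$x_mm)
  expect_equal(back$prescription_cgy, plan$prescription_cgy)

  cp <- file.path(dir, "plan.csv")
  write_spot_csv(plan, cp)
  back2 <- read_spot_csv(cp)
  expect_identical(back2$spots$mu, plan$spots$mu)
  expect_identical(back2$spots$energy_mev, plan$spots$energy_mev)
  expect_identical(back2$beams$gantry_deg, plan$beams$gantry_deg)
  expect_true(back2$normalized)
})
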
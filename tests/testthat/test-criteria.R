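test_that("metric classification respects the printed inequalities", {
  tb <- criteria_table()
  # coverage: CR1 is inclusive at the bound
  expect_equal(classify_metric(98.4, "d95_pct", tb), "CR1")
  expect_equal(classify_metric(98.0, "d95_pct", tb), "CR1")
  expect_equal(classify_metric(97.5, "d95_pct", tb), "CR2")
  expect_equal(classify_metric(96.99, "d95_pct", tb), "fail")
  expect_equal(classify_metric(97.0, "d99_pct", tb), "CR1")
  expect_equal(classify_metric(96.0, "d99_pct", tb), "CR2")
  # change metrics: CR1 is strict, the boundary value falls in CR2
  expect_equal(classify_metric(1.49, "delta_d1_pct", tb), "CR1")
  expect_equal(classify_metric(1.5, "delta_d1_pct", tb), "CR2")
  expect_equal(classify_metric(2.0, "delta_d1_pct", tb), "CR2")
  expect_equal(classify_metric(2.5, "delta_d1_pct", tb), "fail")
  expect_equal(classify_metric(0.030, "delta_hi", tb), "CR2")
  expect_equal(classify_metric(0.05, "delta_hi", tb), "fail")
  expect_equal(classify_metric(2.0, "delta_davg_pct", tb), "CR2")
  # bandwidths in cGy
  expect_equal(classify_metric(99.9, "bw_avg_coverage_cgy", tb), "CR1")
  expect_equal(classify_metric(100, "bw_avg_coverage_cgy", tb), "CR2")
  expect_equal(classify_metric(150, "bw_avg_highdose_cgy", tb), "fail")
  expect_error(classify_metric(1, "not_a_metric", tb), "unknown metric")
})

test_that("criteria table round-trips through JSON and validates CR2", {
  tb <- criteria_table()
  expect_equal(nrow(tb), 7)
  path <- withr::local_tempfile(fileext = ".json")
  write_criteria_json(tb, path)
  back <- read_criteria_json(path)
  expect_equal(as.data.frame(back), as.data.frame(tb))
  expect_error(criteria_table(d95_cr2_pct = 99), "weaker")
})

test_that("plan outcome follows the all-CR1 / five-CR1-all-CR2 rules", {
  v7 <- function(...) c(...)
  expect_equal(repaintr:::verdict_from_classes(rep("CR1", 7)), "acceptable")
  expect_equal(repaintr:::verdict_from_classes(
    v7("CR1", "CR1", "CR1", "CR1", "CR1", "CR2", "CR2")),
    "acceptable_minor_deviation")
  expect_equal(repaintr:::verdict_from_classes(
    v7("CR1", "CR1", "CR1", "CR1", "CR1", "CR1", "fail")),
    "unacceptable")
  expect_equal(repaintr:::verdict_from_classes(
    v7("CR1", "CR1", "CR1", "CR1", "CR2", "CR2", "CR2")),
    "unacceptable")  # only four CR1
})

test_that("verdict of a metric set is pure and tidy-accessible", {
  n <- 300
  nom <- rep(7000, n)
  scen <- matrix(7000, n, 10)
  ms <- compute_metric_set(nom, scen)
  v1 <- evaluate_plan(ms)
  v2 <- evaluate_plan(ms)
  expect_identical(as.data.frame(v1), as.data.frame(v2))
  expect_equal(attr(v1, "outcome"), "acceptable")
  g <- glance(v1)
  expect_equal(g$n_cr1, 7)
  expect_equal(g$outcome, "acceptable")
})

test_that("escalation returns the minimal acceptable X with a full trace", {
  ph <- static_phantom()
  plan <- static_plan()
  sw <- find_optimal_repaintings(plan, ph, x_max = 4)
  expect_equal(sw$optimal_x, 1)
  expect_equal(sw$outcome, "acceptable")
  expect_equal(length(sw$verdicts), 1)  # stops at the first acceptable X
  td <- tidy(sw)
  expect_equal(unique(td$x), 1)
  expect_true(all(td$class == "CR1"))
  # unnormalized plans are refused
  un <- plan; un$normalized <- FALSE
  expect_error(find_optimal_repaintings(un, ph), "normalized")
})

test_that("a moving target needs more than one painting", {
  ph <- fixture("moving10_phantom", function() {
    generate_phantom(phantom_config(ctv_volume_cc = 22, spacing_mm = 4,
                                    motion_mm = c(0, 0, 10), seed = 3))
  })
  plan <- fixture("moving10_plan", function() generate_sfud_plan(ph, 2))
  sw <- find_optimal_repaintings(plan, ph, x_max = 2)
  # escalation bookkeeping: X = 1 tried first and not acceptable
  expect_gte(length(sw$verdicts), 2)
  expect_false(attr(sw$verdicts[[1]], "outcome") == "acceptable")
  expect_true(all(tidy(sw)$x %in% 1:2))
})
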
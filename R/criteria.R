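#' Two-tier plan acceptance criteria table
#'
#' The seven evaluation metrics each carry a primary bound (CR1) and a
#' weaker secondary interval (CR2).  Coverage metrics are lower bounds in
#' percent of the prescription (CR1 inclusive: D95% exactly 98% passes);
#' the change and bandwidth metrics are upper bounds with a strict CR1
#' (a dD1% of exactly 1.5% falls in CR2).  The boundary value dHI = 0.030
#' is assigned to CR2 (closed lower bound) so that the classification is
#' total.
#'
#' @param d95_cr1_pct,d95_cr2_pct D95% bounds, percent of D_Rx.
#' @param d99_cr1_pct,d99_cr2_pct D99% bounds, percent of D_Rx.
#' @param delta_d1_cr1,delta_d1_cr2 Hot-spot change bounds, percent.
#' @param delta_davg_cr1,delta_davg_cr2 Mean coverage-change bounds,
#'   percent.
#' @param delta_hi_cr1,delta_hi_cr2 Homogeneity-change bounds.
#' @param bw_cr1_cgy,bw_cr2_cgy Bandwidth bounds (both regions), cGy.
#' @return A tibble of class `criteria_table` with columns `metric`,
#'   `direction` (`"ge"` lower bound / `"lt"` upper bound), `cr1`, `cr2`.
#' @examples
#' criteria_table()
#' @export
criteria_table <- function(d95_cr1_pct = 98, d95_cr2_pct = 97,
                           d99_cr1_pct = 97, d99_cr2_pct = 96,
                           delta_d1_cr1 = 1.5, delta_d1_cr2 = 2.5,
                           delta_davg_cr1 = 2, delta_davg_cr2 = 2.5,
                           delta_hi_cr1 = 0.030, delta_hi_cr2 = 0.040,
                           bw_cr1_cgy = 100, bw_cr2_cgy = 150) {
  tbl <- tibble(
    metric = c("d95_pct", "d99_pct", "delta_d1_pct", "delta_davg_pct",
               "delta_hi", "bw_avg_coverage_cgy", "bw_avg_highdose_cgy"),
    direction = c("ge", "ge", "lt", "lt", "lt", "lt", "lt"),
    cr1 = c(d95_cr1_pct, d99_cr1_pct, delta_d1_cr1, delta_davg_cr1,
            delta_hi_cr1, bw_cr1_cgy, bw_cr1_cgy),
    cr2 = c(d95_cr2_pct, d99_cr2_pct, delta_d1_cr2, delta_davg_cr2,
            delta_hi_cr2, bw_cr2_cgy, bw_cr2_cgy)
  )
  weaker <- ifelse(tbl$direction == "ge", tbl$cr2 < tbl$cr1, tbl$cr2 > tbl$cr1)
  if (!all(weaker)) abort("each CR2 bound must be strictly weaker than CR1")
  structure(tbl, class = c("criteria_table", class(tbl)))
}

#' Classify one metric value against the criteria
#'
#' @param value Metric value.
#' @param metric Metric id (a `metric` entry of [criteria_table()]).
#' @param table A [criteria_table()].
#' @return `"CR1"`, `"CR2"` or `"fail"`.
#' @examples
#' classify_metric(98.4, "d95_pct")   # CR1
#' classify_metric(2.0, "delta_d1_pct")  # CR2
#' @export
classify_metric <- function(value, metric, table = criteria_table()) {
  row <- table[table$metric == metric, ]
  if (nrow(row) != 1) abort(sprintf("unknown metric id '%s'", metric))
  if (row$direction == "ge") {
    if (value >= row$cr1) "CR1" else if (value >= row$cr2) "CR2" else "fail"
  } else {
    if (value < row$cr1) "CR1" else if (value < row$cr2) "CR2" else "fail"
  }
}

# outcome from the seven per-metric classes: all CR1 -> acceptable;
# at least five CR1 and none failing -> acceptable with minor deviation
verdict_from_classes <- function(classes) {
  stopifnot(length(classes) == 7,
            all(classes %in% c("CR1", "CR2", "fail")))
  n_cr1 <- sum(classes == "CR1")
  if (n_cr1 == 7) {
    "acceptable"
  } else if (n_cr1 >= 5 && !any(classes == "fail")) {
    "acceptable_minor_deviation"
  } else {
    "unacceptable"
  }
}

#' Evaluate a metric set against the acceptance criteria
#'
#' A plan is *acceptable* when all seven metrics meet CR1, *acceptable
#' with a minor deviation* when at least five meet CR1 and every metric
#' meets at least CR2 (metrics already in CR1 count as meeting CR2), and
#' *unacceptable* otherwise.  The verdict is a pure function of the
#' metric set.
#'
#' @param ms A [compute_metric_set()] result.
#' @param table A [criteria_table()].
#' @return An object of class `plan_verdict`: tibble `metric`, `value`,
#'   `class`, with the `outcome` as an attribute (see
#'   [glance.plan_verdict()]).
#' @export
evaluate_plan <- function(ms, table = criteria_table()) {
  stopifnot(inherits(ms, "metric_set"))
  td <- tidy(ms)
  td$class <- vapply(seq_len(nrow(td)), function(i) {
    classify_metric(td$value[i], td$metric[i], table)
  }, character(1))
  structure(td,
            class = c("plan_verdict", class(td)),
            outcome = verdict_from_classes(td$class))
}

#' @export
print.plan_verdict <- function(x, ...) {
  cat(sprintf("<plan_verdict> outcome: %s\n", attr(x, "outcome")))
  NextMethod()
}

#' One-row summary of a plan verdict
#'
#' @param x A `plan_verdict`.
#' @param ... Unused.
#' @return Tibble `outcome`, `n_cr1`, `n_cr2`, `n_fail`.
#' @export
glance.plan_verdict <- function(x, ...) {
  tibble(
    outcome = attr(x, "outcome"),
    n_cr1 = sum(x$class == "CR1"),
    n_cr2 = sum(x$class == "CR2"),
    n_fail = sum(x$class == "fail")
  )
}

#' Escalate repaintings until the plan is acceptable
#'
#' Runs the full interplay evaluation for X = 1, 2, ... paintings and
#' stops at the smallest X whose verdict is *acceptable*.  If no X up to
#' `x_max` is acceptable the verdict at `x_max` (minor deviation or
#' unacceptable) is reported.  The complete per-X metric trace is
#' retained.
#'
#' @param plan A normalized `pbs_plan`.
#' @param phantom A `phantom_4d`.
#' @param machine A [machine_model()].
#' @param bragg A [bragg_model()].
#' @param table A [criteria_table()].
#' @param x_max Maximum number of paintings to try (10, the machine
#'   limit, by default).
#' @return An object of class `repaint_sweep`: `optimal_x`, `outcome`,
#'   `verdicts` (list by X), `metrics` (list of `metric_set` by X),
#'   `delivery` (per-X, per-beam minutes); see [tidy.repaint_sweep()].
#' @export
find_optimal_repaintings <- function(plan, phantom,
                                     machine = machine_model(),
                                     bragg = bragg_model(),
                                     table = criteria_table(),
                                     x_max = 10) {
  stopifnot(inherits(plan, "pbs_plan"))
  if (!isTRUE(plan$normalized)) {
    abort("plan must be normalized before interplay evaluation")
  }
  verdicts <- list(); metrics <- list(); delivery <- list()
  optimal_x <- NA_integer_
  outcome <- "unacceptable"
  for (X in seq_len(x_max)) {
    rp <- build_vrx_plan(plan, X, machine)
    res <- run_all_scenarios(rp, phantom, machine, bragg)
    ms <- compute_metric_set(res$nominal, res$scenarios, plan$prescription_cgy)
    v <- evaluate_plan(ms, table)
    verdicts[[X]] <- v
    metrics[[X]] <- ms
    delivery[[X]] <- dplyr::mutate(res$delivery, x = X, .before = 1)
    outcome <- attr(v, "outcome")
    if (outcome == "acceptable") {
      optimal_x <- X
      break
    }
  }
  if (is.na(optimal_x)) optimal_x <- length(verdicts)
  structure(
    list(
      optimal_x = optimal_x,
      outcome = outcome,
      verdicts = verdicts,
      metrics = metrics,
      delivery = dplyr::bind_rows(delivery),
      criteria = table
    ),
    class = "repaint_sweep"
  )
}

#' @export
print.repaint_sweep <- function(x, ...) {
  cat(sprintf("<repaint_sweep> tried X = 1..%d; outcome '%s' at X* = %d\n",
              length(x$verdicts), x$outcome, x$optimal_x))
  invisible(x)
}

#' Tidy the per-X metric trace of a repainting sweep
#'
#' @param x A `repaint_sweep`.
#' @param ... Unused.
#' @return Tibble `x` (paintings), `metric`, `value`, `class`, `outcome`.
#' @export
tidy.repaint_sweep <- function(x, ...) {
  purrr::map_dfr(seq_along(x$verdicts), function(X) {
    v <- x$verdicts[[X]]
    dplyr::mutate(as_tibble(v), x = X, outcome = attr(v, "outcome"),
                  .before = 1)
  })
}

#' One-row summary of a repainting sweep
#'
#' @param x A `repaint_sweep`.
#' @param ... Unused.
#' @return Tibble `optimal_x`, `outcome`, `n_tried`, `max_minutes`.
#' @export
glance.repaint_sweep <- function(x, ...) {
  tibble(
    optimal_x = x$optimal_x,
    outcome = x$outcome,
    n_tried = length(x$verdicts),
    max_minutes = max(x$delivery$minutes)
  )
}
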
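#' Dose received by at least X% of the volume (D_X%)
#'
#' For equal-volume voxels the cumulative DVH is a step function; D_X% is
#' the largest dose level received by at least X% of the voxels, i.e. the
#' `ceiling(X*n/100)`-th largest voxel dose.  This inverse-cumulative
#' convention matches a brute-force cumulative dose histogram evaluated
#' at arbitrarily fine bins.
#'
#' @param doses Numeric vector of voxel doses (equal volumes), cGy.
#' @param volume_pct Volume percentage X, in (0, 100] (vectorized).
#' @return Dose in cGy, one value per element of `volume_pct`.
#' @examples
#' dose_at_volume(c(7000, 6900, 6800, 6700), 50)  # 6900
#' @export
dose_at_volume <- function(doses, volume_pct) {
  doses <- as.numeric(doses)
  n <- length(doses)
  if (n == 0) abort("empty dose array")
  if (any(volume_pct <= 0 | volume_pct > 100)) {
    abort("`volume_pct` must be in (0, 100]")
  }
  sorted <- sort(doses, decreasing = TRUE)
  m <- pmin(n, pmax(1L, ceiling(volume_pct * n / 100 - 1e-9)))
  sorted[m]
}

#' Homogeneity index D99%/D1%
#'
#' Ratio of the near-minimum to the near-maximum CTV dose; 1 for a
#' perfectly uniform distribution, smaller for hotter/colder plans.
#' Invariant under uniform dose scaling.
#'
#' @param doses Numeric vector of voxel doses.
#' @return HI in (0, 1] for any physical distribution.
#' @export
homogeneity_index <- function(doses) {
  d1 <- dose_at_volume(doses, 1)
  if (d1 <= 0) abort("D1% is zero; homogeneity index undefined")
  dose_at_volume(doses, 99) / d1
}

#' Worst-case-scenario value across starting phases
#'
#' For a metric evaluated in each of the ten starting-phase scenarios,
#' the WCS is the least favorable value: the minimum for coverage
#' metrics (D95%...D99%) and for the homogeneity index, the maximum for
#' the hot-spot D1%.
#'
#' @param values Per-scenario metric values (exactly 10 unless
#'   `strict = FALSE`).
#' @param kind `"coverage"`, `"hotspot"` or `"hi"`.
#' @param strict Require exactly ten scenarios.
#' @return The WCS value.
#' @export
wcs_select <- function(values, kind = c("coverage", "hotspot", "hi"),
                       strict = TRUE) {
  kind <- match.arg(kind)
  if (strict && length(values) != 10) {
    abort("WCS evaluation requires exactly 10 starting-phase scenarios")
  }
  switch(kind, coverage = min(values), hi = min(values), hotspot = max(values))
}

#' Interplay metric set from nominal and scenario doses
#'
#' Computes the seven plan-evaluation metrics from the nominal
#' (motion-free) dose and the ten starting-phase scenario doses:
#'
#' * WCS D95% and D99% as a percentage of the prescription;
#' * the hot-spot change `dD1% = (D1%_WCS - D1%_nom) / D1%_nom * 100`
#'   (normalized by the nominal D1%, not the prescription);
#' * the homogeneity change `dHI = HI_nom - HI_WCS`;
#' * the mean coverage change `dDavg` of
#'   `dDX% = (DX%_nom - DX%_WCS) / D_Rx * 100` over X = 95..99
#'   (normalized by the prescription);
#' * the mean DVH bandwidth (max - min of DX% across the ten scenarios)
#'   over X = 95..99 (target coverage) and over X = 1..5 (high-dose
#'   region), in cGy.
#'
#' @param nominal Nominal voxel dose vector, cGy.
#' @param scenarios Matrix (voxels x scenarios) or list of dose vectors.
#' @param d_rx Prescription dose, cGy(RBE).
#' @param strict Require exactly ten scenarios.
#' @return An object of class `metric_set`; see [tidy.metric_set()].
#' @export
compute_metric_set <- function(nominal, scenarios, d_rx = 7000,
                               strict = TRUE) {
  if (is.list(scenarios)) scenarios <- do.call(cbind, scenarios)
  scenarios <- as.matrix(scenarios)
  if (length(nominal) != nrow(scenarios)) {
    abort("nominal and scenario doses must have the same voxel count")
  }
  ns <- ncol(scenarios)
  if (strict && ns != 10) {
    abort("metric evaluation requires exactly 10 starting-phase scenarios")
  }
  cov_x <- 95:99
  hot_x <- 1:5
  per_scen <- purrr::map_dfr(seq_len(ns), function(s) {
    d <- scenarios[, s]
    tibble(
      scenario = s - 1L,
      x_pct = c(cov_x, hot_x),
      region = rep(c("coverage", "highdose"), c(length(cov_x), length(hot_x))),
      dose_cgy = dose_at_volume(d, c(cov_x, hot_x))
    )
  })
  hi_scen <- apply(scenarios, 2, homogeneity_index)

  dx_wcs <- per_scen %>%
    group_by(.data$x_pct, .data$region) %>%
    summarise(wcs = min(.data$dose_cgy), max = max(.data$dose_cgy),
              bw = max(.data$dose_cgy) - min(.data$dose_cgy),
              .groups = "drop")
  cov_tbl <- dx_wcs[dx_wcs$region == "coverage", ]
  hot_tbl <- dx_wcs[dx_wcs$region == "highdose", ]

  nom_dx <- setNames(dose_at_volume(nominal, cov_x), cov_x)
  d1_nom <- dose_at_volume(nominal, 1)
  d1_wcs <- max(vapply(seq_len(ns), function(s) dose_at_volume(scenarios[, s], 1),
                       numeric(1)))
  hi_nom <- homogeneity_index(nominal)

  d95_wcs <- cov_tbl$wcs[cov_tbl$x_pct == 95]
  d99_wcs <- cov_tbl$wcs[cov_tbl$x_pct == 99]
  delta_dx <- (nom_dx - cov_tbl$wcs[match(cov_x, cov_tbl$x_pct)]) / d_rx * 100

  structure(
    list(
      d_rx = d_rx,
      d95_wcs_cgy = d95_wcs,
      d99_wcs_cgy = d99_wcs,
      d95_pct = d95_wcs / d_rx * 100,
      d99_pct = d99_wcs / d_rx * 100,
      delta_d1_pct = (d1_wcs - d1_nom) / d1_nom * 100,
      delta_hi = hi_nom - wcs_select(hi_scen, "hi", strict = FALSE),
      delta_davg_pct = mean(delta_dx),
      bw_avg_coverage_cgy = mean(cov_tbl$bw[match(cov_x, cov_tbl$x_pct)]),
      bw_avg_highdose_cgy = mean(hot_tbl$bw[match(hot_x, hot_tbl$x_pct)]),
      d1_nominal_cgy = d1_nom,
      d1_wcs_cgy = d1_wcs,
      hi_nominal = hi_nom,
      hi_wcs = wcs_select(hi_scen, "hi", strict = FALSE),
      per_scenario = per_scen,
      per_scenario_hi = tibble(scenario = seq_len(ns) - 1L, hi = hi_scen)
    ),
    class = "metric_set"
  )
}

#' @export
print.metric_set <- function(x, ...) {
  cat("<metric_set>\n")
  cat(sprintf("  WCS D95%% = %.1f cGy (%.2f%% of D_Rx), WCS D99%% = %.1f cGy (%.2f%%)\n",
              x$d95_wcs_cgy, x$d95_pct, x$d99_wcs_cgy, x$d99_pct))
  cat(sprintf("  dD1%% = %.3f%%, dHI = %.4f, dDavg = %.3f%%\n",
              x$delta_d1_pct, x$delta_hi, x$delta_davg_pct))
  cat(sprintf("  BWavg coverage = %.1f cGy, BWavg high-dose = %.1f cGy\n",
              x$bw_avg_coverage_cgy, x$bw_avg_highdose_cgy))
  invisible(x)
}

#' Tidy the seven evaluation metrics
#'
#' @param x A `metric_set`.
#' @param ... Unused.
#' @return Tibble `metric`, `value`.
#' @export
tidy.metric_set <- function(x, ...) {
  tibble(
    metric = c("d95_pct", "d99_pct", "delta_d1_pct", "delta_davg_pct",
               "delta_hi", "bw_avg_coverage_cgy", "bw_avg_highdose_cgy"),
    value = c(x$d95_pct, x$d99_pct, x$delta_d1_pct, x$delta_davg_pct,
              x$delta_hi, x$bw_avg_coverage_cgy, x$bw_avg_highdose_cgy)
  )
}

#' Mean cumulative DVH across scenarios
#'
#' Pointwise mean of the scenarios' cumulative volume-fraction curves on
#' a common dose grid (the blue dashed "average interplay DVH" of a
#' scenario plot).
#'
#' @param scenarios Matrix (voxels x scenarios) or list of equal-length
#'   dose vectors.
#' @param grid Optional dose grid, cGy; defaults to 512 points spanning
#'   the scenarios.
#' @return Tibble `dose_cgy`, `volume_fraction`.
#' @export
mean_dvh <- function(scenarios, grid = NULL) {
  if (is.list(scenarios)) {
    if (length(unique(lengths(scenarios))) != 1) {
      abort("scenario dose vectors must have equal voxel counts")
    }
    scenarios <- do.call(cbind, scenarios)
  }
  scenarios <- as.matrix(scenarios)
  if (is.null(grid)) {
    grid <- seq(0, max(scenarios) * 1.02, length.out = 512)
  }
  vf <- vapply(seq_len(ncol(scenarios)), function(s) {
    vapply(grid, function(g) mean(scenarios[, s] >= g), numeric(1))
  }, numeric(length(grid)))
  tibble(dose_cgy = grid, volume_fraction = rowMeans(vf))
}

#' Cumulative DVH curve of one dose distribution
#'
#' @param doses Voxel dose vector, cGy.
#' @param grid Optional dose grid; defaults to the sorted unique doses.
#' @return Tibble `dose_cgy`, `volume_fraction`.
#' @export
dvh_curve <- function(doses, grid = NULL) {
  if (is.null(grid)) grid <- sort(unique(c(0, doses)))
  tibble(
    dose_cgy = grid,
    volume_fraction = vapply(grid, function(g) mean(doses >= g), numeric(1))
  )
}
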
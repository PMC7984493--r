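#' Breathing phase active at a time point
#'
#' Phases advance cyclically with equal dwell time `period / n_phases`;
#' delivery may begin in any phase of the cycle, which is the random
#' variable the ten-scenario evaluation sweeps over.
#'
#' @param t Time since the start of delivery, s (vectorized).
#' @param period Breathing period, s.
#' @param starting_phase Phase index (0-based) active at `t = 0`.
#' @param n_phases Number of phases in the cycle.
#' @return Integer phase indices.
#' @examples
#' phase_at_time(1.0, period = 4, starting_phase = 3)  # 5
#' @export
phase_at_time <- function(t, period, starting_phase, n_phases = 10) {
  if (period <= 0) abort("`period` must be positive")
  stopifnot(starting_phase >= 0, starting_phase < n_phases)
  if (any(t < 0)) abort("`t` must be non-negative")
  as.integer((starting_phase + floor(t / (period / n_phases))) %% n_phases)
}

# per-(beam, phase) geometry cache reused across scenarios
build_geometry_cache <- function(phantom, beams) {
  phases <- phantom$displacements$phase
  cache <- vector("list", nrow(beams))
  for (b in seq_len(nrow(beams))) {
    cache[[b]] <- lapply(phases, function(k) {
      beam_geometry(phantom, beams$gantry_deg[b],
                    unname(target_displacement(phantom, k)))
    })
    names(cache[[b]]) <- as.character(phases)
  }
  cache
}

#' Accumulate the interplay dose of one delivery scenario
#'
#' Plays the timed delivery sequence against the breathing phantom: each
#' sub-spot's dose is computed in the geometry of the phase active at its
#' temporal midpoint (spot durations of a few ms are far shorter than the
#' ~0.4 s phase dwell) and scored back to the reference-frame CTV voxels
#' through the rigid displacement, then scaled to the full course.  Every
#' field starts its clock at the scenario's starting phase.
#'
#' @param timeline A [build_timeline()] result.
#' @param phantom A `phantom_4d`.
#' @param starting_phase Starting phase index, 0-based.
#' @param bragg A [bragg_model()].
#' @param geometry_cache Optional precomputed per-(beam, phase) geometry
#'   cache (built internally when `NULL`; [run_all_scenarios()] builds
#'   it once and shares it across the ten scenarios).
#' @return An object of class `scenario_result`: `dose` (tibble `voxel`,
#'   `dose_cgy`, course-level), `phase_mu` (tibble `phase`, `mu`: MU
#'   delivered while each phase was active, per fraction) and
#'   `starting_phase`.
#' @export
accumulate_interplay_dose <- function(timeline, phantom, starting_phase,
                                      bragg = bragg_model(),
                                      geometry_cache = NULL) {
  stopifnot(inherits(timeline, "timed_sequence"),
            inherits(phantom, "phantom_4d"))
  beams <- attr(timeline, "beams")
  machine <- attr(timeline, "machine")
  n_fractions <- attr(timeline, "n_fractions")
  if (is.null(geometry_cache)) {
    geometry_cache <- build_geometry_cache(phantom, beams)
  }
  period <- phantom$config$period_s
  n_phases <- phantom$config$n_phases

  tl <- as_tibble(timeline)
  tl$phase <- phase_at_time(tl$t_start_s + tl$duration_s / 2,
                            period, starting_phase, n_phases)

  dose <- numeric(nrow(phantom$voxels))
  groups <- split(seq_len(nrow(tl)),
                  list(tl$beam, tl$phase, tl$energy_mev), drop = TRUE)
  for (idx in groups) {
    b <- tl$beam[idx[1]]
    k <- tl$phase[idx[1]]
    e <- tl$energy_mev[idx[1]]
    geom <- geometry_cache[[match(b, beams$beam)]][[as.character(k)]]
    r <- range_from_energy(e, bragg, machine$max_energy_mev)
    dose <- dose + layer_dose_vec(geom, tl$x_mm[idx], tl$y_mm[idx],
                                  tl$mu[idx], r, bragg, machine)
  }
  phase_mu <- tl %>%
    group_by(phase = .data$phase) %>%
    summarise(mu = sum(.data$mu), .groups = "drop")

  structure(
    list(
      dose = tibble(voxel = phantom$voxels$voxel,
                    dose_cgy = dose * n_fractions),
      phase_mu = phase_mu,
      starting_phase = as.integer(starting_phase)
    ),
    class = "scenario_result"
  )
}

#' Run the full ten-scenario interplay evaluation
#'
#' Simulates time-resolved delivery of a repainted plan for each of the
#' ten breathing starting phases and computes the motion-free nominal
#' reference dose, the inputs of the worst-case-scenario and bandwidth
#' metrics.  Deterministic given its inputs.
#'
#' @param rp A `vrx_plan`.
#' @param phantom A `phantom_4d`.
#' @param machine A [machine_model()].
#' @param bragg A [bragg_model()].
#' @return An object of class `interplay_result`: `nominal` (dose
#'   vector, cGy, per reference voxel), `scenarios` (matrix voxels x
#'   starting phases), `phase_mu` (per-scenario MU bookkeeping tibble),
#'   `delivery` (per-beam minutes), `n_paintings`.
#' @export
run_all_scenarios <- function(rp, phantom, machine = machine_model(),
                              bragg = bragg_model()) {
  stopifnot(inherits(rp, "vrx_plan"), inherits(phantom, "phantom_4d"))
  timeline <- build_timeline(rp, machine)
  cache <- build_geometry_cache(phantom, rp$beams)
  n_phases <- phantom$config$n_phases

  nominal_plan <- pbs_plan(rp$nominal_spots, rp$beams,
                           rp$prescription_cgy, rp$fraction_cgy,
                           normalized = TRUE)
  nominal <- static_dose(nominal_plan, phantom, "reference", bragg, machine)

  scen <- lapply(seq_len(n_phases) - 1, function(s) {
    accumulate_interplay_dose(timeline, phantom, s, bragg, cache)
  })
  scenarios <- vapply(scen, function(x) x$dose$dose_cgy,
                      numeric(nrow(phantom$voxels)))
  colnames(scenarios) <- paste0("phase", seq_len(n_phases) - 1)
  phase_mu <- purrr::map_dfr(scen, function(x) {
    dplyr::mutate(x$phase_mu, starting_phase = x$starting_phase, .before = 1)
  })

  structure(
    list(
      nominal = nominal$dose_cgy,
      scenarios = scenarios,
      phase_mu = phase_mu,
      delivery = beam_delivery_time(timeline),
      n_paintings = rp$n_paintings,
      voxels = phantom$voxels
    ),
    class = "interplay_result"
  )
}

#' @export
print.interplay_result <- function(x, ...) {
  cat(sprintf("<interplay_result> VR%d: %d voxels x %d starting phases\n",
              x$n_paintings, nrow(x$scenarios), ncol(x$scenarios)))
  cat(sprintf("  nominal D99 = %.1f cGy; scenario D99 range %.1f-%.1f cGy\n",
              dose_at_volume(x$nominal, 99),
              min(apply(x$scenarios, 2, dose_at_volume, 99)),
              max(apply(x$scenarios, 2, dose_at_volume, 99))))
  invisible(x)
}

#' @describeIn run_all_scenarios Tidy per-scenario voxel doses.
#' @param x An `interplay_result`.
#' @param ... Unused.
#' @export
as_tibble.interplay_result <- function(x, ...) {
  out <- as_tibble(x$scenarios)
  out$voxel <- x$voxels$voxel
  out$nominal_cgy <- x$nominal
  tidyr::pivot_longer(out, dplyr::starts_with("phase"),
                      names_to = "starting_phase", names_prefix = "phase",
                      values_to = "dose_cgy") %>%
    mutate(starting_phase = as.integer(.data$starting_phase))
}
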
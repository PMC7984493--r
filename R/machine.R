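#' Machine delivery time-structure and beam-optics model
#'
#' Parameters of the PBS delivery system used throughout the simulation:
#' the scanning speed between spots, the dose-rate surrogate (spot dwell
#' time per monitor unit), the smallest spot weight the machine can
#' deliver, the energy-layer switching time, and the in-air spot size at
#' isocenter.  Defaults describe a modern gantry with fast layer switching
#' in both the "down" (high to low energy) and "up" directions, which is
#' what makes alternating-order volumetric repainting deliverable.
#'
#' @param inter_spot_speed_cm_s Lateral scanning-magnet speed between
#'   spots, cm/s.
#' @param spot_time_ms_per_mu Spot delivery (dwell) time per monitor unit,
#'   ms/MU.
#' @param min_spot_mu Minimum deliverable spot weight, MU.  Every sub-spot
#'   emitted by the repainting sequencer must be at least this heavy.
#' @param layer_switch_s Energy-layer switching time, seconds, applied at
#'   every energy change ("down" direction).
#' @param layer_switch_up_s Switching time in the "up" direction; defaults
#'   to `layer_switch_s` (a single symmetric value).
#' @param sigma_air_mm In-air one-sigma spot size at isocenter, mm, for
#'   the highest energy.
#' @param max_energy_mev Highest deliverable proton energy, MeV.
#'
#' @return An object of class `machine_model` (a named list).
#' @examples
#' machine_model()
#' @export
machine_model <- function(inter_spot_speed_cm_s = 250,
                          spot_time_ms_per_mu = 4,
                          min_spot_mu = 0.015,
                          layer_switch_s = 1,
                          layer_switch_up_s = NULL,
                          sigma_air_mm = 3,
                          max_energy_mev = 226.5) {
  if (is.null(layer_switch_up_s)) layer_switch_up_s <- layer_switch_s
  m <- list(
    inter_spot_speed_cm_s = inter_spot_speed_cm_s,
    spot_time_ms_per_mu = spot_time_ms_per_mu,
    min_spot_mu = min_spot_mu,
    layer_switch_s = layer_switch_s,
    layer_switch_up_s = layer_switch_up_s,
    sigma_air_mm = sigma_air_mm,
    max_energy_mev = max_energy_mev
  )
  bad <- names(m)[!vapply(m, function(x) is.numeric(x) && length(x) == 1 && x > 0, logical(1))]
  if (length(bad) > 0) {
    abort(paste0("machine_model parameters must be positive scalars: ",
                 paste(bad, collapse = ", ")))
  }
  structure(m, class = "machine_model")
}

#' @export
print.machine_model <- function(x, ...) {
  cat("<machine_model>\n")
  cat(sprintf("  scan speed between spots : %g cm/s\n", x$inter_spot_speed_cm_s))
  cat(sprintf("  spot delivery time       : %g ms/MU\n", x$spot_time_ms_per_mu))
  cat(sprintf("  minimum spot weight      : %g MU\n", x$min_spot_mu))
  cat(sprintf("  layer switch (down/up)   : %g s / %g s\n",
              x$layer_switch_s, x$layer_switch_up_s))
  cat(sprintf("  in-air sigma at iso      : %g mm (at %g MeV)\n",
              x$sigma_air_mm, x$max_energy_mev))
  invisible(x)
}
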
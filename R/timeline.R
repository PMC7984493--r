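#' Absolute delivery timestamps of a repainted plan
#'
#' Converts a delivery sequence into per-sub-spot start times using the
#' machine time structure: each spot dwells `mu x spot_time_ms_per_mu`,
#' the beam then travels to the next spot at the inter-spot scanning
#' speed (beam off, no dose), and every energy change costs the layer
#' switching time.  At a painting junction the same energy is delivered
#' twice in a row, so no switch is inserted there — the economy that
#' makes the alternating order attractive.  Each beam's clock starts at
#' zero at its first spot.
#'
#' @param rp A `vrx_plan` (a VR1 plan is the nominal case).
#' @param machine A [machine_model()].
#' @return An object of class `timed_sequence`: tibble `beam`, `seq`,
#'   `t_start_s`, `duration_s`, `painting`, `layer`, `energy_mev`,
#'   `x_mm`, `y_mm`, `mu`, `spot_id`, with the beam table, fraction count
#'   and machine attached as attributes.
#' @export
build_timeline <- function(rp, machine = machine_model()) {
  stopifnot(inherits(rp, "vrx_plan"))
  d <- rp$delivery %>% arrange(.data$beam, .data$seq)
  out <- d %>%
    group_by(.data$beam) %>%
    mutate(
      duration_s = .data$mu * machine$spot_time_ms_per_mu / 1000,
      energy_prev = lag(.data$energy_mev),
      dist_mm = sqrt((.data$x_mm - lag(.data$x_mm))^2 +
                     (.data$y_mm - lag(.data$y_mm))^2),
      up_switch = lag(.data$painting) %% 2 == 0 &
        .data$energy_mev > .data$energy_prev,
      gap_s = dplyr::case_when(
        is.na(.data$energy_prev) ~ 0,
        .data$energy_mev != .data$energy_prev & .data$up_switch ~
          machine$layer_switch_up_s,
        .data$energy_mev != .data$energy_prev ~ machine$layer_switch_s,
        TRUE ~ .data$dist_mm / 10 / machine$inter_spot_speed_cm_s
      ),
      t_start_s = cumsum(.data$gap_s + lag(.data$duration_s, default = 0))
    ) %>%
    ungroup() %>%
    select("beam", "seq", "t_start_s", "duration_s", "painting", "layer",
           "energy_mev", "x_mm", "y_mm", "mu", "spot_id")
  structure(
    out,
    class = c("timed_sequence", class(out)),
    beams = rp$beams,
    n_fractions = rp$n_fractions,
    n_paintings = rp$n_paintings,
    machine = machine
  )
}

#' Beam delivery time
#'
#' Total delivery time per beam — the last sub-spot's start time plus its
#' duration — in minutes.
#'
#' @param ts A [build_timeline()] result.
#' @return Tibble `beam`, `minutes`.
#' @export
beam_delivery_time <- function(ts) {
  stopifnot(inherits(ts, "timed_sequence"))
  ts %>%
    group_by(.data$beam) %>%
    summarise(minutes = (max(.data$t_start_s + .data$duration_s)) / 60,
              .groups = "drop")
}

#' Export a delivery timeline as CSV
#'
#' @param ts A `timed_sequence`.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_timeline_csv <- function(ts, path) {
  stopifnot(inherits(ts, "timed_sequence"))
  readr::write_csv(as_tibble(ts), path)
  invisible(path)
}
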
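# shared fixtures, built lazily once per test session

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

small_phantom <- function() {
  fixture("small_phantom", function() {
    generate_phantom(phantom_config(ctv_volume_cc = 22, spacing_mm = 4,
                                    motion_mm = c(2, 2, 8), seed = 7))
  })
}

static_phantom <- function() {
  fixture("static_phantom", function() {
    generate_phantom(phantom_config(ctv_volume_cc = 22, spacing_mm = 4,
                                    motion_mm = c(0, 0, 0), seed = 7))
  })
}

# normalized two-beam SFUD plan on the small moving phantom
small_plan <- function() {
  fixture("small_plan", function() generate_sfud_plan(small_phantom(), 2))
}

# normalized plan on the static phantom
static_plan <- function() {
  fixture("static_plan", function() generate_sfud_plan(static_phantom(), 2))
}

# hand-built multi-layer toy plan (energies descending distal -> proximal)
toy_plan <- function(energies = c(120, 100, 80), spots_per_layer = 2,
                     mu = 0.1, spacing_mm = 5) {
  spots <- purrr::map_dfr(seq_along(energies), function(l) {
    tibble::tibble(
      beam = 1L, layer = l, energy_mev = energies[l],
      x_mm = (seq_len(spots_per_layer) - 1) * spacing_mm,
      y_mm = 0, mu = mu
    )
  })
  pbs_plan(spots, tibble::tibble(beam = 1L, gantry_deg = 0))
}

# independent delivery-time oracle: replay the sequence row by row,
# summing dwell, travel and switch increments
oracle_beam_seconds <- function(delivery, machine) {
  t <- 0
  for (i in seq_len(nrow(delivery))) {
    if (i > 1) {
      if (delivery$energy_mev[i] != delivery$energy_mev[i - 1]) {
        t <- t + machine$layer_switch_s
      } else {
        d_mm <- sqrt((delivery$x_mm[i] - delivery$x_mm[i - 1])^2 +
                       (delivery$y_mm[i] - delivery$y_mm[i - 1])^2)
        t <- t + d_mm / 10 / machine$inter_spot_speed_cm_s
      }
    }
    t <- t + delivery$mu[i] * machine$spot_time_ms_per_mu / 1000
  }
  t
}

# brute-force cumulative-histogram D_X%: the largest dose level on a
# 0.01-cGy grid received by at least X% of the voxels
oracle_dose_at_volume <- function(doses, x_pct) {
  n <- length(doses)
  m <- ceiling(x_pct * n / 100 - 1e-9)
  grid <- seq(0, max(doses) + 0.01, by = 0.01)
  cnt <- n - findInterval(grid - 1e-9, sort(doses))
  max(grid[cnt >= m])
}
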
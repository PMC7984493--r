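#' Planning configuration for the simplified SFUD generator
#'
#' Surrogate rules for the parts of treatment planning a commercial TPS
#' automates: energy-layer spacing equal to the 80%-80% Bragg-peak width,
#' a constant lateral spot grid expressed in units of the in-air sigma,
#' and margins that extend spot coverage slightly beyond the CTV so edge
#' voxels can be made uniform.
#'
#' @param gantry_angles_deg Candidate coplanar gantry angles; the first
#'   `n_beams` are used.
#' @param spot_spacing_sigma Lateral spot grid spacing in units of the
#'   in-air sigma.
#' @param lateral_margin_mm Spots are kept if within this lateral
#'   distance of any CTV voxel of the layer.
#' @param layer_margin_widths Extra range margin beyond the CTV's WEPL
#'   extent, in units of the 80-80 Bragg width, on each side.
#' @param layer_band_widths Half-width (in 80-80 widths) of the WEPL band
#'   around a layer's range used to pick which voxels define its lateral
#'   spot extent.
#' @param opt_iterations Iterations of the multiplicative nonnegative
#'   least-squares weight update.
#' @param uniformity_cv_max Intended upper bound on the per-beam CTV dose
#'   coefficient of variation (SFUD property); checked by
#'   [plan_uniformity()], not enforced.
#' @return An object of class `planning_config`.
#' @export
planning_config <- function(gantry_angles_deg = c(0, 90, 180),
                           spot_spacing_sigma = 1,
                           lateral_margin_mm = 4,
                           layer_margin_widths = 0.6,
                           layer_band_widths = 0.75,
                           opt_iterations = 200,
                           uniformity_cv_max = 0.05) {
  stopifnot(spot_spacing_sigma > 0, lateral_margin_mm >= 0,
            layer_margin_widths >= 0, layer_band_widths > 0,
            opt_iterations >= 1)
  structure(
    list(
      gantry_angles_deg = gantry_angles_deg,
      spot_spacing_sigma = spot_spacing_sigma,
      lateral_margin_mm = lateral_margin_mm,
      layer_margin_widths = layer_margin_widths,
      layer_band_widths = layer_band_widths,
      opt_iterations = as.integer(opt_iterations),
      uniformity_cv_max = uniformity_cv_max
    ),
    class = "planning_config"
  )
}

#' Construct a PBS plan object
#'
#' A plan is a spot table (beam, energy layer, lateral position, monitor
#' units) plus the beam directions and the prescription.  Within each
#' beam the nominal delivery order is by layer with strictly descending
#' energy (the "down" direction) and serpentine spot order within a
#' layer.
#'
#' @param spots Tibble with columns `beam`, `layer`, `energy_mev`,
#'   `x_mm`, `y_mm`, `mu` (layer 1 = most distal).
#' @param beams Tibble with columns `beam`, `gantry_deg`.
#' @param prescription_cgy Total course prescription to the CTV, cGy(RBE).
#' @param fraction_cgy Dose per fraction, cGy(RBE).
#' @param normalized Whether [normalize_plan()] has been applied.
#' @return An object of class `pbs_plan`.
#' @export
pbs_plan <- function(spots, beams, prescription_cgy = 7000,
                     fraction_cgy = 200, normalized = FALSE) {
  stopifnot(is.data.frame(spots), is.data.frame(beams),
            all(c("beam", "layer", "energy_mev", "x_mm", "y_mm", "mu") %in% names(spots)),
            all(c("beam", "gantry_deg") %in% names(beams)),
            prescription_cgy > 0, fraction_cgy > 0)
  if (prescription_cgy %% fraction_cgy != 0) {
    abort("`prescription_cgy` must be a whole number of fractions")
  }
  spots <- as_tibble(spots)
  for (b in unique(spots$beam)) {
    e <- spots$energy_mev[spots$beam == b]
    l <- spots$layer[spots$beam == b]
    by_layer <- vapply(split(e, l), function(x) x[1], numeric(1))
    by_layer <- by_layer[order(as.integer(names(by_layer)))]
    if (any(diff(by_layer) >= 0)) {
      abort(sprintf("beam %s: layer energies must be strictly descending (distal to proximal)", b))
    }
  }
  structure(
    list(
      spots = spots,
      beams = as_tibble(beams),
      prescription_cgy = prescription_cgy,
      fraction_cgy = fraction_cgy,
      n_fractions = as.integer(round(prescription_cgy / fraction_cgy)),
      normalized = normalized
    ),
    class = "pbs_plan"
  )
}

#' @export
print.pbs_plan <- function(x, ...) {
  st <- plan_statistics(x)
  cat("<pbs_plan>\n")
  cat(sprintf("  prescription: %g cGy(RBE) in %d x %g cGy fractions%s\n",
              x$prescription_cgy, x$n_fractions, x$fraction_cgy,
              if (isTRUE(x$normalized)) " (normalized)" else ""))
  for (i in seq_len(nrow(st))) {
    cat(sprintf("  beam %d (gantry %g deg): %d layers, %d spots, %.2f MU/fraction\n",
                st$beam[i], x$beams$gantry_deg[i], st$n_layers[i],
                st$n_spots[i], st$total_mu[i]))
  }
  invisible(x)
}

# serpentine within-layer order: rows by v, u alternating by row; the
# same order is used for every painting
serpentine_order <- function(x, y, row_height) {
  row <- as.integer(round(y / row_height))
  ord <- order(row, ifelse(row %% 2 == 0, x, -x))
  ord
}

# geometric spot/layer skeleton of one beam with unit weights
beam_skeleton <- function(phantom, gantry_deg, machine, bragg, config) {
  geom <- beam_geometry(phantom, gantry_deg)
  width <- bragg_width_8080_mm(bragg)
  margin <- config$layer_margin_widths * width
  r_distal <- max(geom$wepl_mm) + margin
  r_prox <- min(geom$wepl_mm) - margin
  ranges_mm <- seq(r_distal, r_prox, by = -width)
  energies <- energy_from_range(ranges_mm / 10, bragg)
  if (any(energies > machine$max_energy_mev)) {
    abort(sprintf(
      "CTV at WEPL %.1f mm is beyond the reach of the %g MeV maximum energy",
      r_distal, machine$max_energy_mev))
  }
  g <- config$spot_spacing_sigma * machine$sigma_air_mm
  gx <- seq(floor(min(geom$u_mm) / g) - 1, ceiling(max(geom$u_mm) / g) + 1) * g
  gy <- seq(floor(min(geom$v_mm) / g) - 1, ceiling(max(geom$v_mm) / g) + 1) * g
  grid <- expand.grid(x_mm = gx, y_mm = gy, KEEP.OUT.ATTRS = FALSE)

  band <- config$layer_band_widths * width
  keep_margin <- config$lateral_margin_mm
  layers <- purrr::map_dfr(seq_along(ranges_mm), function(i) {
    sel <- abs(geom$wepl_mm - ranges_mm[i]) <= band
    if (!any(sel)) return(NULL)
    u <- geom$u_mm[sel]; v <- geom$v_mm[sel]
    # keep grid points within the lateral margin of any in-band voxel
    d2 <- outer(grid$x_mm, u, "-")^2 + outer(grid$y_mm, v, "-")^2
    ok <- matrixStats_rowMins(d2) <= keep_margin^2
    if (!any(ok)) return(NULL)
    xs <- grid$x_mm[ok]; ys <- grid$y_mm[ok]
    ord <- serpentine_order(xs, ys, g)
    tibble(layer = i, energy_mev = energies[i],
           x_mm = xs[ord], y_mm = ys[ord], mu = 1)
  })
  list(spots = layers, geom = geom)
}

# row minima without extra dependencies
matrixStats_rowMins <- function(m) {
  do.call(pmin, c(as.data.frame(m), list(na.rm = TRUE)))
}

#' Nonnegative least-squares spot weights
#'
#' Solves `min ||A w - d||^2, w >= 0` by multiplicative (image-space
#' reconstruction) updates `w <- w * (A'd) / (A'Aw)`, which are monotone
#' in the objective and preserve nonnegativity when `A` and `d` are
#' nonnegative.  The start is the best uniform scalar weight, so the
#' returned objective never exceeds the uniform-weight baseline.
#'
#' @param A Unit-weight dose matrix (points x spots), nonnegative.
#' @param d Target dose per point.
#' @param iterations Number of updates.
#' @return Nonnegative weight vector, one per column of `A`.
#' @export
nnls_weights <- function(A, d, iterations = 200) {
  A <- as.matrix(A)
  stopifnot(all(A >= 0), all(d >= 0), nrow(A) == length(d))
  a1 <- rowSums(A)
  denom0 <- sum(a1^2)
  if (denom0 == 0) abort("all-zero dose matrix: no spot reaches any point")
  w <- rep(sum(a1 * d) / denom0, ncol(A))
  atd <- as.numeric(crossprod(A, d))
  eps <- 1e-300
  for (i in seq_len(iterations)) {
    ata_w <- as.numeric(crossprod(A, A %*% w))
    w <- w * (atd + eps) / (ata_w + eps)
  }
  w
}

#' Optimize spot weights of a plan
#'
#' Per-beam nonnegative least-squares fit of the CTV voxel doses (in the
#' motion-free reference geometry) to a uniform target of
#' `fraction_cgy / n_beams` per beam — each field alone delivers a
#' near-uniform CTV dose, the SFUD property.  Spots whose optimized
#' weight falls below the machine minimum MU are removed and the
#' remaining weights re-solved once; any stragglers are then clipped up
#' to the minimum.
#'
#' @param plan A `pbs_plan` (e.g. a unit-weight skeleton).
#' @param phantom A `phantom_4d`.
#' @param bragg A [bragg_model()].
#' @param machine A [machine_model()].
#' @param config A [planning_config()].
#' @return The plan with optimized weights (`normalized` reset to FALSE).
#' @export
optimize_spot_weights <- function(plan, phantom, bragg = bragg_model(),
                                  machine = machine_model(),
                                  config = planning_config()) {
  stopifnot(inherits(plan, "pbs_plan"))
  target <- plan$fraction_cgy / nrow(plan$beams)
  out <- purrr::map_dfr(seq_len(nrow(plan$beams)), function(b) {
    sb <- plan$spots[plan$spots$beam == plan$beams$beam[b], ]
    geom <- beam_geometry(phantom, plan$beams$gantry_deg[b])
    solve_beam <- function(sp) {
      A <- build_dose_matrix(sp, geom, bragg, machine)
      nnls_weights(A, rep(target, nrow(geom)), config$opt_iterations)
    }
    w <- solve_beam(sb)
    low <- w < machine$min_spot_mu
    if (any(low)) {
      sb <- sb[!low, , drop = FALSE]
      w <- solve_beam(sb)
      w <- pmax(w, machine$min_spot_mu)
    }
    sb$mu <- w
    sb
  })
  pbs_plan(out, plan$beams, plan$prescription_cgy, plan$fraction_cgy,
           normalized = FALSE)
}

# unit-MU dose matrix of a whole beam's spot table
build_dose_matrix <- function(spots, geom, bragg, machine) {
  blocks <- lapply(split(seq_len(nrow(spots)), spots$layer), function(idx) {
    e <- spots$energy_mev[idx[1]]
    r <- range_from_energy(e, bragg, machine$max_energy_mev)
    layer_dose_matrix(geom, spots$x_mm[idx], spots$y_mm[idx], r, bragg, machine)
  })
  A <- do.call(cbind, blocks)
  # restore original column order (split() groups by layer, already ordered)
  ord <- unlist(split(seq_len(nrow(spots)), spots$layer), use.names = FALSE)
  A[, order(ord), drop = FALSE]
}

#' Generate a simplified SFUD plan on the reference phase
#'
#' Places energy layers to cover the CTV's water-equivalent depth extent
#' (uniform spacing equal to the 80-80 Bragg width, the basis of the
#' automatic TPS rule) and a constant lateral spot grid per layer, then
#' optimizes spot weights per beam and normalizes the plan so that 99%
#' of the CTV receives 99% of the prescription (6930 cGy(RBE) for the
#' 7000 cGy default).
#'
#' @param phantom A `phantom_4d`.
#' @param n_beams Number of proton fields, 2 or 3.
#' @param machine A [machine_model()].
#' @param bragg A [bragg_model()].
#' @param config A [planning_config()].
#' @param prescription_cgy,fraction_cgy Prescription, cGy(RBE).
#' @return A normalized `pbs_plan`.
#' @export
generate_sfud_plan <- function(phantom, n_beams = 2,
                               machine = machine_model(),
                               bragg = bragg_model(),
                               config = planning_config(),
                               prescription_cgy = 7000,
                               fraction_cgy = 200) {
  stopifnot(inherits(phantom, "phantom_4d"))
  if (!(n_beams %in% 2:3)) abort("`n_beams` must be 2 or 3 (SFUD technique)")
  angles <- config$gantry_angles_deg[seq_len(n_beams)]
  spots <- purrr::map_dfr(seq_len(n_beams), function(b) {
    sk <- beam_skeleton(phantom, angles[b], machine, bragg, config)
    dplyr::mutate(sk$spots, beam = b, .before = 1)
  })
  beams <- tibble(beam = seq_len(n_beams), gantry_deg = angles)
  plan <- pbs_plan(spots, beams, prescription_cgy, fraction_cgy)
  plan <- optimize_spot_weights(plan, phantom, bragg, machine, config)
  normalize_plan(plan, phantom, bragg = bragg, machine = machine)
}

#' Normalize a plan to the prescription coverage level
#'
#' Scales every spot's MU by a single factor so that the dose received by
#' 99% of the CTV (D99%) in the nominal static reference-phase
#' distribution equals `d99_target` — 99% of the 7000 cGy(RBE)
#' prescription by default.  Because dose is linear in MU the scaling is
#' exact, and normalizing twice is the identity.
#'
#' @param plan A `pbs_plan`.
#' @param phantom A `phantom_4d`.
#' @param nominal Optional precomputed nominal [static_dose()] tibble.
#' @param d99_target Target D99% of the CTV, cGy(RBE).
#' @param bragg A [bragg_model()].
#' @param machine A [machine_model()].
#' @return The normalized plan.
#' @export
normalize_plan <- function(plan, phantom, nominal = NULL, d99_target = 6930,
                           bragg = bragg_model(), machine = machine_model()) {
  stopifnot(inherits(plan, "pbs_plan"))
  if (is.null(nominal)) {
    nominal <- static_dose(plan, phantom, "reference", bragg, machine)
  }
  d99 <- dose_at_volume(nominal$dose_cgy, 99)
  if (d99 <= 0) abort("nominal D99% is zero; cannot normalize")
  scale <- d99_target / d99
  plan$spots$mu <- plan$spots$mu * scale
  low <- sum(plan$spots$mu < machine$min_spot_mu * (1 - 1e-9))
  if (low > 0) {
    warn(sprintf("%d spots fell below the minimum MU after normalization", low))
  }
  plan$normalized <- TRUE
  plan
}

#' Per-beam plan statistics
#'
#' Counts delivered energy layers, spots and total MU per beam, for a
#' nominal plan or a repainted plan (where a layer delivered in several
#' paintings counts once per painting in which it has surviving spots).
#'
#' @param plan A `pbs_plan` or `vrx_plan`.
#' @return Tibble `beam`, `n_layers`, `n_spots`, `total_mu`.
#' @export
plan_statistics <- function(plan) {
  if (inherits(plan, "vrx_plan")) {
    dl <- plan$delivery
    if (nrow(dl) == 0) abort("empty plan")
    return(dl %>%
      group_by(.data$beam) %>%
      summarise(
        n_layers = dplyr::n_distinct(paste(.data$painting, .data$layer)),
        n_spots = dplyr::n(),
        total_mu = sum(.data$mu),
        .groups = "drop"
      ))
  }
  stopifnot(inherits(plan, "pbs_plan"))
  if (nrow(plan$spots) == 0) abort("empty plan")
  counts <- plan$spots %>%
    group_by(.data$beam) %>%
    summarise(
      n_layers = dplyr::n_distinct(.data$layer),
      n_spots = dplyr::n(),
      total_mu = sum(.data$mu),
      .groups = "drop"
    )
  if (any(!(plan$beams$beam %in% counts$beam))) abort("empty beam in plan")
  counts
}

#' Per-beam CTV dose uniformity (SFUD check)
#'
#' Coefficient of variation of each beam's own CTV dose on the reference
#' phase; the SFUD technique requires each field alone to be nearly
#' uniform.
#'
#' @inheritParams optimize_spot_weights
#' @return Tibble `beam`, `mean_cgy`, `cv`.
#' @export
plan_uniformity <- function(plan, phantom, bragg = bragg_model(),
                            machine = machine_model()) {
  stopifnot(inherits(plan, "pbs_plan"))
  purrr::map_dfr(seq_len(nrow(plan$beams)), function(b) {
    sb <- plan$spots[plan$spots$beam == plan$beams$beam[b], ]
    geom <- beam_geometry(phantom, plan$beams$gantry_deg[b])
    dose <- numeric(nrow(geom))
    for (e in unique(sb$energy_mev)) {
      sl <- sb[sb$energy_mev == e, ]
      r <- range_from_energy(e, bragg, machine$max_energy_mev)
      dose <- dose + layer_dose_vec(geom, sl$x_mm, sl$y_mm, sl$mu, r, bragg, machine)
    }
    tibble(beam = plan$beams$beam[b], mean_cgy = mean(dose),
           cv = stats::sd(dose) / mean(dose))
  })
}
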
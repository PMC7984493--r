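#' Analytic Bragg-peak pencil-beam model
#'
#' A desk-scale analytic dose kernel: a Bragg-Kleeman power-law
#' range-energy relation, a parameterized depth-dose curve (entrance
#' plateau rising into a Gaussian peak at the nominal range with a
#' Gaussian distal falloff), and a lateral Gaussian whose sigma grows
#' linearly with depth in quadrature with the in-air spot size.  All
#' metrics downstream are relative/DVH-based, so a smooth analytic kernel
#' is sufficient; it is not a transport calculation.
#'
#' @param alpha_cm_mev Bragg-Kleeman coefficient, cm/MeV^p (water).
#' @param exponent Bragg-Kleeman exponent p.
#' @param distal_sigma_mm Gaussian sigma of the peak/distal falloff, mm.
#' @param entrance_ratio Entrance-plateau to peak dose ratio.
#' @param lateral_growth_mm_per_cm Lateral sigma growth per cm of
#'   water-equivalent depth, mm/cm (added in quadrature to the in-air
#'   sigma).
#' @param dose_scale_cgy Kernel scale, cGy * mm^2 per MU: dose of a 1 MU
#'   spot is `dose_scale_cgy * depth_dose * gaussian_2d` with the
#'   normalized 2D Gaussian in mm^-2.  Chosen so that clinically typical
#'   fraction doses come out at per-fraction spot weights around
#'   0.1-0.3 MU (total ~100-200 MU per field), well above the machine
#'   minimum MU.
#'
#' @return An object of class `bragg_model`.
#' @examples
#' range_from_energy(100, bragg_model())  # ~7.6 cm in water
#' @export
bragg_model <- function(alpha_cm_mev = 0.0022,
                        exponent = 1.77,
                        distal_sigma_mm = 2.2,
                        entrance_ratio = 0.3,
                        lateral_growth_mm_per_cm = 0.5,
                        dose_scale_cgy = 5e3) {
  stopifnot(alpha_cm_mev > 0, exponent > 0, distal_sigma_mm > 0,
            entrance_ratio > 0, entrance_ratio < 1,
            lateral_growth_mm_per_cm >= 0, dose_scale_cgy > 0)
  structure(
    list(
      alpha_cm_mev = alpha_cm_mev,
      exponent = exponent,
      distal_sigma_mm = distal_sigma_mm,
      entrance_ratio = entrance_ratio,
      lateral_growth_mm_per_cm = lateral_growth_mm_per_cm,
      dose_scale_cgy = dose_scale_cgy
    ),
    class = "bragg_model"
  )
}

#' Proton range in water from energy
#'
#' Bragg-Kleeman power law `R = alpha * E^p`.
#'
#' @param energy_mev Proton energy, MeV (vectorized).
#' @param model A [bragg_model()].
#' @param max_energy_mev Upper bound of the deliverable energy.
#' @return Range in cm of water.
#' @export
range_from_energy <- function(energy_mev, model = bragg_model(),
                              max_energy_mev = 226.5) {
  if (any(energy_mev <= 0 | energy_mev > max_energy_mev)) {
    abort(sprintf("energies must lie in (0, %g] MeV", max_energy_mev))
  }
  model$alpha_cm_mev * energy_mev^model$exponent
}

#' Proton energy from range in water
#'
#' Inverse of [range_from_energy()].
#'
#' @param range_cm Range in cm of water (vectorized).
#' @param model A [bragg_model()].
#' @return Energy in MeV.
#' @export
energy_from_range <- function(range_cm, model = bragg_model()) {
  if (any(range_cm <= 0)) abort("ranges must be positive")
  (range_cm / model$alpha_cm_mev)^(1 / model$exponent)
}

#' Relative depth-dose of a single energy layer
#'
#' Entrance plateau of height `entrance_ratio` rising as a Gaussian into
#' the peak (value 1 exactly at the nominal range) with a pure-Gaussian
#' distal falloff; the dose is below 2% of the peak beyond three distal
#' sigmas.
#'
#' @param z_cm Water-equivalent depth, cm (vectorized).
#' @param range_cm Nominal range of the layer, cm.
#' @param model A [bragg_model()].
#' @return Relative dose in `[0, 1]`.
#' @export
depth_dose <- function(z_cm, range_cm, model = bragg_model()) {
  if (any(z_cm < 0)) abort("depths must be non-negative")
  dz_mm <- (z_cm - range_cm) * 10
  g <- exp(-dz_mm^2 / (2 * model$distal_sigma_mm^2))
  p <- model$entrance_ratio
  ifelse(z_cm <= range_cm, p + (1 - p) * g, g)
}

# 80%-proximal to 80%-distal width of the Bragg peak, mm; this is the
# basis of the automatic energy-layer spacing rule
bragg_width_8080_mm <- function(model) {
  p <- model$entrance_ratio
  s <- model$distal_sigma_mm
  prox <- s * sqrt(2 * log((1 - p) / (0.8 - p)))
  dist <- s * sqrt(2 * log(1 / 0.8))
  prox + dist
}

# orthonormal beam frame for a gantry angle (degrees) in the axial plane:
# `d` points downstream, `u` is the in-plane transverse axis, `w` is SI
beam_frame <- function(gantry_deg) {
  th <- gantry_deg * pi / 180
  list(
    d = c(sin(th), -cos(th), 0),
    u = c(cos(th), sin(th), 0),
    w = c(0, 0, 1)
  )
}

#' Beam's-eye-view geometry of the CTV voxels in one breathing phase
#'
#' Projects the (rigidly displaced) CTV voxel centers into a beam's
#' coordinate frame and computes each voxel's water-equivalent path
#' length (WEPL) by the closed-form line-ellipsoid intersection: entry
#' tissue, then lung at `lung_density`, with the chord of the beam ray
#' inside the (displaced) tumor ellipsoid weighted at `tumor_density`.
#'
#' @param phantom A `phantom_4d`.
#' @param gantry_deg Gantry angle of the beam, degrees.
#' @param displacement Rigid CTV displacement (mm 3-vector) of the phase;
#'   zero is the reference geometry.
#' @return Tibble with one row per voxel: `voxel`, `u_mm`, `v_mm`
#'   (transverse coordinates at isocenter plane), `depth_mm` (geometric
#'   depth past the lung entry plane) and `wepl_mm`.
#' @export
beam_geometry <- function(phantom, gantry_deg, displacement = c(0, 0, 0)) {
  stopifnot(inherits(phantom, "phantom_4d"), length(displacement) == 3)
  cfg <- phantom$config
  fr <- beam_frame(gantry_deg)
  P <- cbind(phantom$voxels$x_mm + displacement[1],
             phantom$voxels$y_mm + displacement[2],
             phantom$voxels$z_mm + displacement[3])
  t_mm <- as.numeric(P %*% fr$d) + cfg$lung_depth_mm
  if (any(t_mm <= 0)) {
    abort("CTV extends upstream of the lung entry plane; increase `lung_depth_mm`")
  }
  # ray from the entry plane point q = p - t*d to the voxel; tumor
  # ellipsoid centered at the displaced centroid with the phantom's axes
  ax <- phantom$axes_mm
  ex <- (P[, 1] - t_mm * fr$d[1] - displacement[1]) / ax[1]
  ey <- (P[, 2] - t_mm * fr$d[2] - displacement[2]) / ax[2]
  ez <- (P[, 3] - t_mm * fr$d[3] - displacement[3]) / ax[3]
  dx <- fr$d[1] / ax[1]; dy <- fr$d[2] / ax[2]; dz <- fr$d[3] / ax[3]
  a <- dx^2 + dy^2 + dz^2
  b <- 2 * (ex * dx + ey * dy + ez * dz)
  c0 <- ex^2 + ey^2 + ez^2 - 1
  disc <- b^2 - 4 * a * c0
  chord <- numeric(length(t_mm))
  hit <- disc > 0
  if (any(hit)) {
    sq <- sqrt(disc[hit])
    s1 <- (-b[hit] - sq) / (2 * a)
    s2 <- (-b[hit] + sq) / (2 * a)
    chord[hit] <- pmax(0, pmin(t_mm[hit], s2) - pmax(0, s1))
  }
  wepl <- cfg$entry_wepl_mm + cfg$lung_density * (t_mm - chord) +
    cfg$tumor_density * chord
  tibble(
    voxel = phantom$voxels$voxel,
    u_mm = as.numeric(P %*% fr$u),
    v_mm = as.numeric(P %*% fr$w),
    depth_mm = t_mm,
    wepl_mm = wepl
  )
}

# depth-dependent lateral variance (mm^2) at a WEPL depth
lateral_sigma2 <- function(wepl_mm, machine, bragg) {
  machine$sigma_air_mm^2 + (bragg$lateral_growth_mm_per_cm * wepl_mm / 10)^2
}

# dose (cGy) at every geometry row from one energy layer's spots.
# xs, ys, mus: spot positions (mm) and weights (MU) at the iso plane.
layer_dose_vec <- function(geom, xs, ys, mus, range_cm, bragg, machine) {
  dd <- depth_dose(geom$wepl_mm / 10, range_cm, bragg)
  sig2 <- lateral_sigma2(geom$wepl_mm, machine, bragg)
  du2 <- outer(geom$u_mm, xs, "-")^2 + outer(geom$v_mm, ys, "-")^2
  g <- exp(-du2 / (2 * sig2))
  bragg$dose_scale_cgy * dd / (2 * pi * sig2) * as.numeric(g %*% mus)
}

# unit-MU dose matrix (n_voxels x n_spots) for one layer; used by the
# spot-weight optimizer
layer_dose_matrix <- function(geom, xs, ys, range_cm, bragg, machine) {
  dd <- depth_dose(geom$wepl_mm / 10, range_cm, bragg)
  sig2 <- lateral_sigma2(geom$wepl_mm, machine, bragg)
  du2 <- outer(geom$u_mm, xs, "-")^2 + outer(geom$v_mm, ys, "-")^2
  bragg$dose_scale_cgy * dd / (2 * pi * sig2) * exp(-du2 / (2 * sig2))
}

#' Dose of a single spot at arbitrary points
#'
#' Evaluates the analytic kernel `mu * depth_dose(WEPL, R) * G2(lateral)`
#' for one spot against a beam's-eye-view geometry table.
#'
#' @param x_mm,y_mm Spot position at the isocenter plane, mm.
#' @param mu Spot weight, MU.
#' @param energy_mev Layer energy, MeV.
#' @param geom A [beam_geometry()] tibble for the points of interest.
#' @param bragg A [bragg_model()].
#' @param machine A [machine_model()].
#' @return Numeric dose (cGy) per geometry row.
#' @export
spot_dose_at_points <- function(x_mm, y_mm, mu, energy_mev, geom,
                                bragg = bragg_model(),
                                machine = machine_model()) {
  r <- range_from_energy(energy_mev, bragg, machine$max_energy_mev)
  layer_dose_vec(geom, x_mm, y_mm, mu, r, bragg, machine)
}

# dose vector (per reference voxel, single fraction) of a whole plan in a
# fixed geometry given the per-beam geometry tables
plan_dose_vec <- function(plan, geoms, bragg, machine) {
  dose <- numeric(nrow(geoms[[1]]))
  spots <- plan$spots
  for (b in unique(spots$beam)) {
    sb <- spots[spots$beam == b, ]
    geom <- geoms[[match(b, plan$beams$beam)]]
    for (e in unique(sb$energy_mev)) {
      sl <- sb[sb$energy_mev == e, ]
      r <- range_from_energy(e, bragg, machine$max_energy_mev)
      dose <- dose + layer_dose_vec(geom, sl$x_mm, sl$y_mm, sl$mu, r, bragg, machine)
    }
  }
  dose
}

#' Static dose of a plan in a fixed breathing phase
#'
#' Sums all spot doses with the CTV held in the geometry of one phase
#' (or the motion-free reference position), scaled to the full course.
#' The reference-phase distribution is the "nominal" dose used for plan
#' normalization and for all nominal terms of the interplay metrics.
#'
#' @param plan A `pbs_plan`.
#' @param phantom A `phantom_4d`.
#' @param phase `"reference"` (zero displacement) or a 0-based phase
#'   index.
#' @param bragg A [bragg_model()].
#' @param machine A [machine_model()].
#' @return Tibble `voxel`, `x_mm`, `y_mm`, `z_mm`, `dose_cgy` (course
#'   dose, i.e. per-fraction dose times the number of fractions).
#' @export
static_dose <- function(plan, phantom, phase = "reference",
                        bragg = bragg_model(), machine = machine_model()) {
  stopifnot(inherits(plan, "pbs_plan"), inherits(phantom, "phantom_4d"))
  disp <- if (identical(phase, "reference")) {
    c(0, 0, 0)
  } else {
    target_displacement(phantom, phase)
  }
  geoms <- lapply(seq_len(nrow(plan$beams)), function(b) {
    beam_geometry(phantom, plan$beams$gantry_deg[b], disp)
  })
  dose <- plan_dose_vec(plan, geoms, bragg, machine) * plan$n_fractions
  dplyr::bind_cols(phantom$voxels, tibble(dose_cgy = dose))
}
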
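#' Synthetic 4D phantom configuration
#'
#' Describes a moving ellipsoidal clinical target volume (CTV) embedded in
#' a homogeneous lung-like slab, preceded by a water-equivalent entry
#' depth.  The envelope of the defaults follows typical PBS lung cases:
#' CTV volumes of a few tens of cc and peak-to-peak 3D tumor motion
#' between 3 and 15 mm over a ten-phase breathing cycle.
#'
#' @param ctv_volume_cc Target volume in cc; the generated voxelization
#'   reproduces it to within one voxel volume.
#' @param ctv_shape Ellipsoid semi-axis ratios (LR, AP, SI); rescaled so
#'   the analytic ellipsoid has exactly `ctv_volume_cc`.
#' @param motion_mm Peak-to-peak rigid tumor motion, mm, as a 3-vector
#'   (LR, AP, SI).  The reported 3D motion is its Euclidean norm.
#' @param period_s Breathing period in seconds (typical adult
#'   free-breathing value by default).
#' @param n_phases Number of breathing phases; ten-phase binning is the
#'   4DCT standard and the only value accepted unless `relax_phases`.
#' @param lung_density,tumor_density Densities relative to water.
#' @param entry_wepl_mm Water-equivalent depth of tissue traversed before
#'   the beam enters the lung, mm.
#' @param lung_depth_mm Geometric distance from the lung entry plane to
#'   the isocenter (CTV reference centroid), mm.
#' @param spacing_mm Voxel spacing of the CTV dose grid, mm.
#' @param jitter_sd_mm Standard deviation of optional seeded Gaussian
#'   jitter applied to voxel centers, mm (0 disables it; use small
#'   sub-voxel values to emulate contouring/voxelization variability).
#' @param seed Integer seed for the jitter; the rest of the geometry is
#'   deterministic.
#' @param relax_phases Allow `n_phases != 10` (off by default).
#' @param allow_large_motion Allow 3D motion of 15 mm or more; such
#'   targets fall outside the intended motion envelope and are refused
#'   otherwise.
#'
#' @return An object of class `phantom_config`.
#' @examples
#' phantom_config(ctv_volume_cc = 22.1, motion_mm = c(3, 2, 12))
#' @export
phantom_config <- function(ctv_volume_cc = 30,
                           ctv_shape = c(1, 1, 1),
                           motion_mm = c(2, 2, 8),
                           period_s = 4,
                           n_phases = 10,
                           lung_density = 0.26,
                           tumor_density = 1,
                           entry_wepl_mm = 50,
                           lung_depth_mm = 80,
                           spacing_mm = 3,
                           jitter_sd_mm = 0,
                           seed = 1L,
                           relax_phases = FALSE,
                           allow_large_motion = FALSE) {
  stopifnot(length(ctv_shape) == 3, length(motion_mm) == 3)
  if (ctv_volume_cc <= 0) abort("`ctv_volume_cc` must be positive")
  if (period_s <= 0) abort("`period_s` must be positive")
  if (spacing_mm <= 0) abort("`spacing_mm` must be positive")
  if (!(lung_density > 0 && lung_density < tumor_density && tumor_density <= 1.2)) {
    abort("densities must satisfy 0 < lung_density < tumor_density <= 1.2")
  }
  if (n_phases != 10 && !relax_phases) {
    abort("`n_phases` must be 10 (4DCT-standard phase binning); set `relax_phases = TRUE` to override")
  }
  if (any(motion_mm < 0)) abort("`motion_mm` components must be non-negative")
  mag <- sqrt(sum(motion_mm^2))
  if (mag >= 15) {
    if (!allow_large_motion) {
      abort("3D tumor motion >= 15 mm is outside the supported envelope; set `allow_large_motion = TRUE` to override")
    }
    warn(sprintf("3D tumor motion %.1f mm exceeds the 15 mm envelope; proceeding on request", mag))
  }
  structure(
    list(
      ctv_volume_cc = ctv_volume_cc,
      ctv_shape = as.numeric(ctv_shape),
      motion_mm = as.numeric(motion_mm),
      period_s = period_s,
      n_phases = as.integer(n_phases),
      lung_density = lung_density,
      tumor_density = tumor_density,
      entry_wepl_mm = entry_wepl_mm,
      lung_depth_mm = lung_depth_mm,
      spacing_mm = spacing_mm,
      jitter_sd_mm = jitter_sd_mm,
      seed = as.integer(seed)
    ),
    class = "phantom_config"
  )
}

#' Generate a synthetic 4D phantom
#'
#' Voxelizes the configured ellipsoidal CTV on a regular grid and attaches
#' the per-phase rigid displacement table of the breathing cycle.  The
#' voxelization selects exactly `round(V / h^3)` voxel centers closest to
#' the ellipsoid (in the ellipsoidal norm), so the generated volume agrees
#' with the request to within one voxel volume.  Per-phase displacement of
#' each axis follows a cosine trajectory `(A/2) * cos(2*pi*k/n)`, the
#' standard surrogate for 4DCT phase binning: phase 0 is one motion
#' extreme, phase `n/2` the opposite, and the mean over phases is zero, so
#' motion oscillates about the reference centroid.
#'
#' @param config A [phantom_config()].
#' @return An object of class `phantom_4d` with elements
#'   `voxels` (tibble: `voxel`, `x_mm`, `y_mm`, `z_mm`),
#'   `displacements` (tibble: `phase`, `dx_mm`, `dy_mm`, `dz_mm`),
#'   `axes_mm` (ellipsoid semi-axes), `voxel_volume_cc`, `phase_duration_s`
#'   and the originating `config`.
#' @examples
#' ph <- generate_phantom(phantom_config(ctv_volume_cc = 25, spacing_mm = 4))
#' nrow(ph$voxels) * ph$voxel_volume_cc  # ~25 cc
#' @export
generate_phantom <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  h <- config$spacing_mm
  v_mm3 <- config$ctv_volume_cc * 1000
  shape <- config$ctv_shape
  scale <- (v_mm3 / (4 / 3 * pi * prod(shape)))^(1 / 3)
  axes <- shape * scale

  # candidate grid centered on the isocenter, generous margin for jitter
  half <- ceiling((axes + 2 * h) / h)
  gx <- seq(-half[1], half[1]) * h
  gy <- seq(-half[2], half[2]) * h
  gz <- seq(-half[3], half[3]) * h
  grid <- expand.grid(x_mm = gx, y_mm = gy, z_mm = gz, KEEP.OUT.ATTRS = FALSE)

  if (config$jitter_sd_mm > 0) {
    jit <- with_seed(config$seed, function() {
      matrix(rnorm(3 * nrow(grid), sd = config$jitter_sd_mm), ncol = 3)
    })
    grid$x_mm <- grid$x_mm + jit[, 1]
    grid$y_mm <- grid$y_mm + jit[, 2]
    grid$z_mm <- grid$z_mm + jit[, 3]
  }

  # exact-count voxelization: keep the m centers innermost in ellipsoidal norm
  m <- max(1L, round(v_mm3 / h^3))
  r2 <- (grid$x_mm / axes[1])^2 + (grid$y_mm / axes[2])^2 + (grid$z_mm / axes[3])^2
  keep <- order(r2)[seq_len(m)]
  keep <- sort(keep)
  voxels <- tibble(
    voxel = seq_len(m),
    x_mm = grid$x_mm[keep],
    y_mm = grid$y_mm[keep],
    z_mm = grid$z_mm[keep]
  )

  k <- seq_len(config$n_phases) - 1
  cosk <- cos(2 * pi * k / config$n_phases)
  displacements <- tibble(
    phase = as.integer(k),
    dx_mm = config$motion_mm[1] / 2 * cosk,
    dy_mm = config$motion_mm[2] / 2 * cosk,
    dz_mm = config$motion_mm[3] / 2 * cosk
  )

  structure(
    list(
      voxels = voxels,
      displacements = displacements,
      axes_mm = axes,
      voxel_volume_cc = h^3 / 1000,
      phase_duration_s = config$period_s / config$n_phases,
      motion_magnitude_mm = sqrt(sum(config$motion_mm^2)),
      config = config
    ),
    class = "phantom_4d"
  )
}

#' @export
print.phantom_4d <- function(x, ...) {
  cat("<phantom_4d>\n")
  cat(sprintf("  CTV: %d voxels of %.3g cc (%.2f cc total), semi-axes %.1f x %.1f x %.1f mm\n",
              nrow(x$voxels), x$voxel_volume_cc,
              nrow(x$voxels) * x$voxel_volume_cc,
              x$axes_mm[1], x$axes_mm[2], x$axes_mm[3]))
  cat(sprintf("  motion (LR, AP, SI): %s mm peak-to-peak, |3D| = %.2f mm\n",
              paste(format(x$config$motion_mm), collapse = ", "),
              x$motion_magnitude_mm))
  cat(sprintf("  breathing: %d phases, period %.2f s\n",
              x$config$n_phases, x$config$period_s))
  invisible(x)
}

#' Rigid CTV displacement of a breathing phase
#'
#' @param phantom A [generate_phantom()] result.
#' @param phase_index Phase index, 0-based (0 to `n_phases - 1`).
#' @return Named numeric 3-vector (`dx_mm`, `dy_mm`, `dz_mm`).
#' @examples
#' ph <- generate_phantom(phantom_config(motion_mm = c(0, 0, 10), spacing_mm = 4))
#' target_displacement(ph, 0)["dz_mm"]  # +5 mm (inhale extreme)
#' @export
target_displacement <- function(phantom, phase_index) {
  stopifnot(inherits(phantom, "phantom_4d"))
  n <- phantom$config$n_phases
  if (length(phase_index) != 1 || phase_index %% 1 != 0 ||
      phase_index < 0 || phase_index >= n) {
    abort(sprintf("`phase_index` must be an integer in [0, %d]", n - 1))
  }
  row <- phantom$displacements[phantom$displacements$phase == phase_index, ]
  c(dx_mm = row$dx_mm, dy_mm = row$dy_mm, dz_mm = row$dz_mm)
}

#' Export a phantom to plain-text files
#'
#' Writes the voxel centers as CSV and the displacement table plus the
#' scalar geometry parameters as JSON.
#'
#' @param phantom A `phantom_4d`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_phantom <- function(phantom, dir) {
  stopifnot(inherits(phantom, "phantom_4d"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  voxel_path <- file.path(dir, "ctv_voxels.csv")
  readr::write_csv(phantom$voxels, voxel_path)
  meta <- list(
    displacements = phantom$displacements,
    axes_mm = phantom$axes_mm,
    voxel_volume_cc = phantom$voxel_volume_cc,
    phase_duration_s = phantom$phase_duration_s,
    config = unclass(phantom$config)
  )
  meta_path <- file.path(dir, "phantom.json")
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(voxel_path, meta_path))
}
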
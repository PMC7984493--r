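# full-precision numeric formatting so text round-trips are lossless
fmt_full <- function(x) {
  ifelse(is.na(x), NA_character_, sprintf("%.17g", x))
}

#' Write and read a plan as JSON
#'
#' The JSON schema is
#' `{prescription_cgy, fraction_cgy, beams: [{gantry_deg, layers:
#' [{energy_mev, spots: [{x_mm, y_mm, mu}]}]}]}`; numbers are written at
#' full precision so a round-trip reproduces the plan bit-exactly.
#'
#' @param plan A `pbs_plan`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_plan_json <- function(plan, path) {
  stopifnot(inherits(plan, "pbs_plan"))
  beams <- lapply(seq_len(nrow(plan$beams)), function(b) {
    sb <- plan$spots[plan$spots$beam == plan$beams$beam[b], ]
    layers <- lapply(sort(unique(sb$layer)), function(l) {
      sl <- sb[sb$layer == l, ]
      list(
        energy_mev = sl$energy_mev[1],
        spots = lapply(seq_len(nrow(sl)), function(i) {
          list(x_mm = sl$x_mm[i], y_mm = sl$y_mm[i], mu = sl$mu[i])
        })
      )
    })
    list(gantry_deg = plan$beams$gantry_deg[b], layers = layers)
  })
  obj <- list(
    prescription_cgy = plan$prescription_cgy,
    fraction_cgy = plan$fraction_cgy,
    normalized = isTRUE(plan$normalized),
    beams = beams
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_plan_json
#' @return `read_plan_json()` returns the reconstructed `pbs_plan`.
#' @export
read_plan_json <- function(path) {
  obj <- jsonlite::read_json(path)
  spots <- purrr::map_dfr(seq_along(obj$beams), function(b) {
    purrr::map_dfr(seq_along(obj$beams[[b]]$layers), function(l) {
      lay <- obj$beams[[b]]$layers[[l]]
      purrr::map_dfr(lay$spots, function(s) {
        tibble(beam = b, layer = l, energy_mev = as.numeric(lay$energy_mev),
               x_mm = as.numeric(s$x_mm), y_mm = as.numeric(s$y_mm),
               mu = as.numeric(s$mu))
      })
    })
  })
  beams <- tibble(
    beam = seq_along(obj$beams),
    gantry_deg = vapply(obj$beams, function(b) b$gantry_deg, numeric(1))
  )
  pbs_plan(spots, beams, obj$prescription_cgy, obj$fraction_cgy,
           normalized = isTRUE(obj$normalized))
}

#' Write and read a plan spot list as CSV
#'
#' Columns `beam`, `layer`, `energy_mev`, `x_mm`, `y_mm`, `mu`; numeric
#' values are written at full precision so the round-trip is lossless.
#' The prescription is carried in a header comment line.
#'
#' @param plan A `pbs_plan`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_spot_csv <- function(plan, path) {
  stopifnot(inherits(plan, "pbs_plan"))
  hdr <- sprintf("# prescription_cgy=%s fraction_cgy=%s gantry_deg=%s normalized=%d",
                 fmt_full(plan$prescription_cgy), fmt_full(plan$fraction_cgy),
                 paste(fmt_full(plan$beams$gantry_deg), collapse = ";"),
                 as.integer(isTRUE(plan$normalized)))
  out <- plan$spots %>%
    mutate(energy_mev = fmt_full(.data$energy_mev),
           x_mm = fmt_full(.data$x_mm),
           y_mm = fmt_full(.data$y_mm),
           mu = fmt_full(.data$mu))
  writeLines(hdr, path)
  readr::write_csv(out, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_spot_csv
#' @return `read_spot_csv()` returns the reconstructed `pbs_plan`.
#' @export
read_spot_csv <- function(path) {
  hdr <- readLines(path, n = 1)
  kv <- regmatches(hdr, gregexpr("[a-z_]+=[^ ]+", hdr))[[1]]
  vals <- setNames(sub("^[a-z_]+=", "", kv), sub("=.*$", "", kv))
  # parse numerics from the printed 17-significant-digit strings ourselves:
  # strtod round-trips exactly
  spots <- readr::read_csv(path, skip = 1, show_col_types = FALSE,
                           col_types = "iicccc")
  for (col in c("energy_mev", "x_mm", "y_mm", "mu")) {
    spots[[col]] <- as.numeric(spots[[col]])
  }
  beams <- tibble(
    beam = sort(unique(spots$beam)),
    gantry_deg = as.numeric(strsplit(vals[["gantry_deg"]], ";")[[1]])
  )
  pbs_plan(spots, beams,
           prescription_cgy = as.numeric(vals[["prescription_cgy"]]),
           fraction_cgy = as.numeric(vals[["fraction_cgy"]]),
           normalized = vals[["normalized"]] == "1")
}

#' Write and read a criteria table as JSON
#'
#' @param table A [criteria_table()].
#' @param path Output path.
#' @return Invisibly, `path`; `read_criteria_json()` returns the table.
#' @export
write_criteria_json <- function(table, path) {
  stopifnot(inherits(table, "criteria_table"))
  jsonlite::write_json(as_tibble(table), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_criteria_json
#' @export
read_criteria_json <- function(path) {
  tbl <- as_tibble(jsonlite::fromJSON(path))
  stopifnot(all(c("metric", "direction", "cr1", "cr2") %in% names(tbl)))
  structure(tbl, class = c("criteria_table", class(tbl)))
}
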
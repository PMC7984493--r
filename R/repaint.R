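#' Split one spot's MU across paintings
#'
#' A spot of weight `w` repainted `X` times should ideally contribute
#' `w/X` in every painting, but no sub-spot may fall below the machine
#' minimum MU `m`.  The spot is therefore split into
#' `k = max(1, min(X, floor(w/m)))` equal parts, so every part stays
#' deliverable, and the `k` parts are spread evenly over the paintings
#' (indices `round(j*X/k)`, `j = 1..k`) to preserve temporal averaging
#' rather than bunching at the start.  The last part absorbs the floating
#' point remainder so the sum reproduces `w` bit-exactly.
#'
#' @param w Spot weight, MU (must itself be deliverable, `w >= m`).
#' @param X Number of paintings.
#' @param m Machine minimum spot MU.
#' @return Tibble `painting`, `mu` with `k` rows.
#' @examples
#' split_spot_mu(0.10, 5)            # five paintings of 0.02
#' split_spot_mu(0.045, 5)           # only three paintings of 0.015 fit
#' @export
split_spot_mu <- function(w, X, m = 0.015) {
  stopifnot(length(w) == 1, length(X) == 1, X >= 1, X == round(X), m > 0)
  if (w < m * (1 - 1e-9)) {
    abort(sprintf("spot weight %g MU is below the machine minimum %g MU", w, m))
  }
  k <- max(1L, min(as.integer(X), as.integer(floor(w / m + 1e-9))))
  part <- w / k
  mu <- rep(part, k)
  mu[k] <- w - sum(mu[seq_len(k - 1)])  # remainder entry: sum(mu) == w exactly
  tibble(painting = as.integer(round(seq_len(k) * X / k)), mu = mu)
}

#' Build a volumetric repainting (VRX) plan with alternating order
#'
#' Transforms a nominal plan (VR1, energy layers delivered distal to
#' proximal, the "down" direction) into a plan with `X` paintings whose
#' layer traversal alternates direction: painting 1 runs down, painting 2
#' up, and so on.  At each painting junction the same energy therefore
#' occurs twice in a row, and no extra layer switch is needed there.
#' Each spot's MU is divided by [split_spot_mu()]; spots too light to
#' appear in all paintings are placed in an evenly spread subset, and
#' layers left with no spots in some painting are skipped entirely.
#' Within a layer the spot scan order is identical in every painting.
#'
#' @param plan A `pbs_plan`.
#' @param X Number of paintings, 1 to 10 (`X = 1` reproduces the nominal
#'   down-only sequence unchanged).
#' @param machine A [machine_model()] (supplies the minimum MU).
#' @return An object of class `vrx_plan`: the per-beam delivery table
#'   (`beam`, `seq`, `painting`, `layer`, `energy_mev`, `x_mm`, `y_mm`,
#'   `mu`, `spot_id`) in delivery order, plus plan metadata.
#' @examples
#' # a 3-layer toy beam repainted twice: energies 120,100,80,80,100,120
#' @export
build_vrx_plan <- function(plan, X, machine = machine_model()) {
  stopifnot(inherits(plan, "pbs_plan"))
  if (!(length(X) == 1 && X == round(X) && X >= 1 && X <= 10)) {
    abort("`X` must be an integer between 1 and 10 paintings")
  }
  X <- as.integer(X)
  spots <- plan$spots
  spots$spot_id <- seq_len(nrow(spots))

  splits <- purrr::map_dfr(seq_len(nrow(spots)), function(i) {
    s <- split_spot_mu(spots$mu[i], X, machine$min_spot_mu)
    s$spot_id <- spots$spot_id[i]
    s
  })
  sub <- dplyr::left_join(splits,
                          dplyr::select(spots, -"mu"),
                          by = "spot_id")

  delivery <- purrr::map_dfr(unique(spots$beam), function(b) {
    sb <- sub[sub$beam == b, ]
    layers <- sort(unique(sb$layer))
    rows <- purrr::map_dfr(seq_len(X), function(p) {
      lp <- if (p %% 2 == 1) layers else rev(layers)
      purrr::map_dfr(lp, function(l) {
        sl <- sb[sb$painting == p & sb$layer == l, ]
        if (nrow(sl) == 0) return(NULL)
        # preserve the nominal within-layer scan order
        sl[order(sl$spot_id), c("painting", "layer", "energy_mev",
                                "x_mm", "y_mm", "mu", "spot_id")]
      })
    })
    dplyr::mutate(rows, beam = b, seq = dplyr::row_number(), .before = 1)
  })

  structure(
    list(
      delivery = delivery,
      beams = plan$beams,
      n_paintings = X,
      prescription_cgy = plan$prescription_cgy,
      fraction_cgy = plan$fraction_cgy,
      n_fractions = plan$n_fractions,
      nominal_spots = spots
    ),
    class = "vrx_plan"
  )
}

#' @export
print.vrx_plan <- function(x, ...) {
  st <- plan_statistics(x)
  cat(sprintf("<vrx_plan> VR%d (alternating order)\n", x$n_paintings))
  for (i in seq_len(nrow(st))) {
    cat(sprintf("  beam %d: %d delivered layers, %d sub-spots, %.2f MU/fraction\n",
                st$beam[i], st$n_layers[i], st$n_spots[i], st$total_mu[i]))
  }
  invisible(x)
}

#' Delivered energy sequence of a repainted beam
#'
#' The per-layer energy sequence in delivery order (consecutive sub-spots
#' of the same layer collapsed), useful for checking the alternating
#' "down"/"up" pattern.
#'
#' @param rp A `vrx_plan`.
#' @param beam Beam number.
#' @return Numeric vector of energies (MeV) in delivery order.
#' @export
energy_sequence <- function(rp, beam = 1) {
  stopifnot(inherits(rp, "vrx_plan"))
  d <- rp$delivery[rp$delivery$beam == beam, ]
  d <- d[order(d$seq), ]
  key <- paste(d$painting, d$layer)
  run_start <- c(TRUE, key[-1] != key[-length(key)])
  d$energy_mev[run_start]
}
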
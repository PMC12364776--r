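#' Delivery-time model parameters
#'
#' Step-and-shoot delivery on an upright positioner: rotational speed 6 deg/s
#' with 5 deg/s^2 acceleration/deceleration, average spot scan speed
#' 600 mm/s, spot delivery current 55 nC/s, energy switching time 0.2 s per
#' layer, and adaptive-aperture leaf speed 500 mm/s for collimated plans.
#'
#' @param rot_speed deg/s. @param rot_accel deg/s^2. @param scan_speed mm/s.
#' @param beam_current nC/s. @param energy_switch s. @param leaf_speed mm/s.
#' @return A `time_model` list.
#' @export
time_model <- function(rot_speed = 6, rot_accel = 5, scan_speed = 600,
                       beam_current = 55, energy_switch = 0.2,
                       leaf_speed = 500) {
  stopifnot(rot_speed > 0, rot_accel > 0, scan_speed > 0, beam_current > 0,
            energy_switch > 0, leaf_speed > 0)
  structure(list(rot_speed = rot_speed, rot_accel = rot_accel,
                 scan_speed = scan_speed, beam_current = beam_current,
                 energy_switch = energy_switch, leaf_speed = leaf_speed),
            class = "time_model")
}

#' Rotation time between directions
#'
#' Trapezoidal velocity profile: `t = delta/v + v/a` when the move reaches
#' full speed (`delta >= v^2/a`), else the triangular profile
#' `t = 2 sqrt(delta/a)`. An 18-degree step at 6 deg/s and 5 deg/s^2 takes
#' 4.2 s.
#'
#' @param delta_angle Rotation magnitude in degrees (>= 0).
#' @param model A [time_model()].
#' @return Time in seconds.
#' @export
rotation_time <- function(delta_angle, model = time_model()) {
  stopifnot(all(delta_angle >= 0))
  v <- model$rot_speed; a <- model$rot_accel
  ifelse(delta_angle >= v^2 / a,
         delta_angle / v + v / a,
         2 * sqrt(delta_angle / a))
}

# serpentine raster order: spots sorted by v rows, alternating u direction
serpentine_order <- function(u, v, eps = 1e-9) {
  vr <- round(v / eps) * eps
  rows <- sort(unique(vr))
  ord <- integer(0)
  for (ri in seq_along(rows)) {
    in_row <- which(vr == rows[ri])
    ord <- c(ord, in_row[order(if (ri %% 2 == 1) u[in_row]
                               else -u[in_row])])
  }
  ord
}

#' Time to deliver one energy layer
#'
#' Energy switching plus serpentine scanning travel plus beam-on time
#' (charge over current), plus collimator leaf travel for collimated plans.
#'
#' @param spots Tibble/data frame with `u`, `v` (cm) and `mu` of the layer's
#'   delivered spots (mu > 0).
#' @param model A [time_model()].
#' @param bm A [beam_model()] (MU to charge conversion).
#' @param leaf_travel Leaf travel distance (cm) to reconfigure the aperture
#'   before this layer; 0 for uncollimated.
#' @return List with `energy_switch`, `scanning`, `beam_on`, `collimator`
#'   and `total` seconds.
#' @export
layer_time <- function(spots, model = time_model(),
                       bm = beam_model_constants(), leaf_travel = 0) {
  scan <- 0
  beam_on <- 0
  if (nrow(spots) > 0) {
    ord <- serpentine_order(spots$u, spots$v)
    uu <- spots$u[ord] * 10  # cm -> mm
    vv <- spots$v[ord] * 10
    if (length(ord) > 1) {
      scan <- sum(sqrt(diff(uu)^2 + diff(vv)^2)) / model$scan_speed
    }
    beam_on <- sum(protons_to_charge(mu_to_protons(spots$mu, bm))) /
      model$beam_current
  }
  coll <- leaf_travel * 10 / model$leaf_speed
  list(energy_switch = model$energy_switch, scanning = scan,
       beam_on = beam_on, collimator = coll,
       total = model$energy_switch + scan + beam_on + coll)
}

#' Plan delivery time with per-component breakdown
#'
#' Sums rotation between consecutive directions (shortest angular path; the
#' move from park position to the first angle is counted as one nominal
#' 360/n step), per-layer energy switching, serpentine scanning, beam-on
#' charge delivery, and (for collimated plans) adaptive-aperture leaf travel.
#' Layers are delivered per direction in decreasing energy order; only spots
#' with positive MU count. The first collimated layer pays full travel from
#' the open position.
#'
#' @param plan An optimized `arc_plan`.
#' @param model A [time_model()].
#' @param bm A [beam_model()] (constants suffice).
#' @return A `time_breakdown`: list with `rotation`, `energy_switch`,
#'   `scanning`, `beam_on`, `collimator`, `total` (s) and a per-layer tibble.
#' @export
plan_time <- function(plan, model = time_model(),
                      bm = beam_model_constants()) {
  stopifnot(inherits(plan, "arc_plan"))
  angles <- plan$angles
  step0 <- if (length(angles) > 1) {
    d <- diff(sort(angles))
    min(360 / length(angles), d[1])
  } else 18
  deltas <- if (length(angles) > 1) {
    raw <- abs(diff(angles))
    pmin(raw, 360 - raw)
  } else numeric(0)
  rot <- sum(rotation_time(c(step0, deltas), model))

  sp <- plan$spots[plan$spots$mu > 0, ]
  comp <- c(energy_switch = 0, scanning = 0, beam_on = 0, collimator = 0)
  rows <- list()
  for (di in seq_along(angles)) {
    lay <- plan$layers[plan$layers$dir_index == di, ]
    lay <- lay[order(-lay$energy), ]
    prev_ap <- NULL
    for (r in seq_len(nrow(lay))) {
      lid <- lay$layer_id[r]
      ls <- sp[sp$layer_id == lid, ]
      if (nrow(ls) == 0) next
      travel <- 0
      if (plan$collimated && !is.null(plan$apertures)) {
        ap <- plan$apertures[[as.character(lid)]]
        if (!is.null(ap)) {
          travel <- if (is.null(prev_ap)) {
            # from open position: half the aperture field extent
            max(ap$nu, ap$nv) * ap$h / 2
          } else {
            aperture_displacement(prev_ap, ap)
          }
          prev_ap <- ap
        }
      }
      lt <- layer_time(ls, model, bm, leaf_travel = travel)
      comp <- comp + c(lt$energy_switch, lt$scanning, lt$beam_on,
                       lt$collimator)
      rows[[length(rows) + 1]] <- tibble::tibble(
        dir_index = di, layer_id = lid, energy = lay$energy[r],
        n_spots = nrow(ls), time_s = lt$total)
    }
  }
  out <- list(rotation = rot,
              energy_switch = unname(comp["energy_switch"]),
              scanning = unname(comp["scanning"]),
              beam_on = unname(comp["beam_on"]),
              collimator = unname(comp["collimator"]),
              total = rot + sum(comp),
              per_layer = dplyr::bind_rows(rows))
  class(out) <- "time_breakdown"
  out
}

#' @export
print.time_breakdown <- function(x, ...) {
  cat("<time_breakdown> total ", round(x$total, 1), " s (rotation ",
      round(x$rotation, 1), ", energy switch ", round(x$energy_switch, 1),
      ", scanning ", round(x$scanning, 1), ", beam-on ",
      round(x$beam_on, 2), ", collimator ", round(x$collimator, 1), ")\n",
      sep = "")
  invisible(x)
}

#' @method tidy time_breakdown
#' @export
tidy.time_breakdown <- function(x, ...) {
  tibble::tibble(
    component = c("rotation", "energy_switch", "scanning", "beam_on",
                  "collimator"),
    seconds = c(x$rotation, x$energy_switch, x$scanning, x$beam_on,
                x$collimator)
  )
}
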
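#' Residual range of a shoot-through spot
#'
#' The water-equivalent range left when a maximum-energy proton exits the
#' patient: `r = R_max - WET(ray)`, with `R_max` the machine's range in water
#' at 230 MeV (a known intrinsic property) and the WET ray-traced through the
#' voxel geometry. A ray missing the body returns `r = R_max`. Negative
#' residual range (proton stops inside) is possible only if `WET > R_max`,
#' which cannot happen for phantom-scale chords.
#'
#' @param grid A [spr_grid()].
#' @param origin,direction Ray(s), as in [wet_along_ray()].
#' @param r_max Range in water of the shoot-through energy (cm).
#' @return Residual range(s) in cm.
#' @export
residual_range <- function(grid, origin, direction, r_max) {
  r_max - wet_along_ray(grid, origin, direction)
}

#' Relative WET difference of a shoot-through spot
#'
#' The per-spot range-verification statistic
#' `(r_plan - r_measured) / (R_max - r_plan)`: the measured-vs-planned
#' residual-range discrepancy normalized by the planned WET. Positive values
#' mean a shorter measured range, i.e. more water-equivalent material in the
#' patient than planned. Undefined when the planned WET vanishes
#' (`R_max = r_plan`, a ray missing the body).
#'
#' @param r_plan,r_measured Residual ranges (cm) from the plan and the
#'   (simulated) measurement.
#' @param r_max Range in water of the shoot-through protons (cm).
#' @return Dimensionless relative WET difference.
#' @export
delta_wet <- function(r_plan, r_measured, r_max) {
  denom <- r_max - r_plan
  if (any(denom <= 0)) {
    stop("R_max must exceed r_plan (zero planned WET is undefined)",
         call. = FALSE)
  }
  (r_plan - r_measured) / denom
}

#' Simulate the range-verification measurement
#'
#' For every shoot-through spot with nonzero MU, ray-traces the residual
#' range on the planning (nominal) geometry and on a perturbed geometry
#' standing in for the measurement, and computes the relative WET difference.
#' Parallel-beam geometry: one ray per ST spot along the direction axis
#' through the spot lattice point. Spots whose planned ray misses the body
#' (planned WET below `wet_min`) have no defined relative difference; they
#' are flagged and report 0.
#'
#' @param plan An `arc_plan` containing ST layers.
#' @param nominal_grid,perturbed_grid [spr_grid()]s for planning and
#'   simulated measurement.
#' @param bm A [beam_model()].
#' @param range_noise_sd Optional Gaussian noise sigma (cm) added to the
#'   measured residual range (ideal detector by default).
#' @param wet_min Planned-WET threshold (cm) below which a spot is flagged
#'   as missing the body.
#' @return A `range_records` tibble: spot_id, dir_index, angle, u, v,
#'   r_plan, r_measured, r_max, delta_wet, flagged.
#' @export
run_verification <- function(plan, nominal_grid, perturbed_grid, bm,
                             range_noise_sd = 0, wet_min = 0.1) {
  stopifnot(inherits(plan, "arc_plan"))
  st <- plan$spots[plan$spots$is_st & plan$spots$mu > 0, ]
  if (nrow(st) == 0) {
    stop("plan has no shoot-through layers to verify", call. = FALSE)
  }
  r_max <- range_in_water(bm$e_max, bm)
  origins <- matrix(0, nrow(st), 3)
  dirs <- matrix(0, nrow(st), 3)
  for (di in unique(st$dir_index)) {
    fr <- beam_frame(plan$angles[di])
    sel <- st$dir_index == di
    origins[sel, ] <- cbind(st$u[sel], st$v[sel], 0) %*%
      rbind(fr$u, fr$v, fr$d) - SOURCE_DIST * matrix(fr$d, sum(sel), 3,
                                                     byrow = TRUE)
    dirs[sel, ] <- matrix(fr$d, sum(sel), 3, byrow = TRUE)
  }
  wet_plan <- wet_along_ray(nominal_grid, origins, dirs)
  wet_meas <- wet_along_ray(perturbed_grid, origins, dirs)
  r_plan <- r_max - wet_plan
  r_meas <- r_max - wet_meas
  if (range_noise_sd > 0) {
    r_meas <- r_meas + stats::rnorm(length(r_meas), 0, range_noise_sd)
  }
  flagged <- wet_plan < wet_min | r_plan < 0 | r_meas < 0
  dw <- rep(0, nrow(st))
  ok <- !flagged
  dw[ok] <- delta_wet(r_plan[ok], r_meas[ok], r_max)
  if (any(r_plan < 0)) {
    warning(sum(r_plan < 0),
            " spot(s) stop inside the body; flagged and excluded")
  }
  out <- tibble::tibble(
    spot_id = st$spot_id, dir_index = st$dir_index, angle = st$angle,
    u = st$u, v = st$v,
    r_plan = r_plan, r_measured = r_meas, r_max = r_max,
    delta_wet = dw, flagged = flagged)
  class(out) <- c("range_records", class(out))
  out
}

#' Per-angle summary of relative WET differences
#'
#' Box-plot statistics per beam angle over the unflagged records: median,
#' quartiles, and whiskers at the most extreme data points within 1.5 IQR of
#' the quartiles.
#'
#' @param records A `range_records` tibble from [run_verification()].
#' @return A `range_summary` tibble: angle, n_spots, median, q1, q3,
#'   whisker_low, whisker_high.
#' @export
summarize_by_angle <- function(records) {
  stopifnot(nrow(records) > 0)
  rec <- records[!records$flagged, ]
  out <- rec |>
    dplyr::group_by(.data$angle) |>
    dplyr::summarise(
      n_spots = dplyr::n(),
      median = stats::median(.data$delta_wet),
      q1 = stats::quantile(.data$delta_wet, 0.25, names = FALSE),
      q3 = stats::quantile(.data$delta_wet, 0.75, names = FALSE),
      whisker_low = min(.data$delta_wet[
        .data$delta_wet >= q1 - 1.5 * (q3 - q1)]),
      whisker_high = max(.data$delta_wet[
        .data$delta_wet <= q3 + 1.5 * (q3 - q1)]),
      .groups = "drop")
  class(out) <- c("range_summary", class(out))
  out
}

#' Spot map of relative WET differences
#'
#' Overlayed per-spot (u, v) positions from all angles with the relative WET
#' difference, capped at +/-15% for display.
#'
#' @param records A `range_records` tibble.
#' @param cap Display cap (default 0.15).
#' @return Tibble: spot_id, angle, u, v, delta_wet, delta_capped.
#' @export
spot_map <- function(records, cap = 0.15) {
  tibble::tibble(
    spot_id = records$spot_id, angle = records$angle,
    u = records$u, v = records$v, delta_wet = records$delta_wet,
    delta_capped = pmin(pmax(records$delta_wet, -cap), cap))
}

#' @method autoplot range_summary
#' @export
autoplot.range_summary <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = factor(.data$angle))) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$whisker_low * 100,
                   ymax = .data$whisker_high * 100), width = 0.3) +
    ggplot2::geom_crossbar(
      ggplot2::aes(y = .data$median * 100, ymin = .data$q1 * 100,
                   ymax = .data$q3 * 100), fill = "grey90") +
    ggplot2::labs(x = "Beam angle (deg)",
                  y = expression(Delta * "WET/WET (%)")) +
    ggplot2::theme_minimal()
}

#' Spot-map display of relative WET differences
#'
#' @param records A `range_records` tibble.
#' @param cap Display cap on |delta| (default 0.15).
#' @return A ggplot: spot positions colored by capped relative WET
#'   difference (red shorter measured range, blue longer).
#' @export
plot_spot_map <- function(records, cap = 0.15) {
  sm <- spot_map(records, cap)
  ggplot2::ggplot(sm, ggplot2::aes(.data$u, .data$v,
                                   colour = .data$delta_capped * 100)) +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::scale_colour_gradient2(low = "blue", mid = "grey80",
                                    high = "red",
                                    limits = c(-cap, cap) * 100,
                                    name = expression(Delta * "WET/WET (%)")) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "u (cm)", y = "v (cm)") +
    ggplot2::theme_minimal()
}
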
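#' Cumulative dose-volume histogram
#'
#' Empirical cumulative DVH on raw voxel dose samples of an ROI: volume
#' fraction receiving at least each dose level.
#'
#' @param dose Dose vector over the scored voxels.
#' @param roi_idx Indices of the ROI's voxels within `dose` (non-empty).
#' @param roi Optional ROI name for labelling.
#' @return A `dvh` object: tibble-backed list with sorted `dose` samples and
#'   the non-increasing `volume` fraction curve.
#' @export
dvh <- function(dose, roi_idx, roi = "ROI") {
  if (length(roi_idx) == 0) stop("empty ROI", call. = FALSE)
  d <- sort(dose[roi_idx], decreasing = TRUE)
  structure(list(roi = roi, samples = d,
                 curve = tibble::tibble(
                   dose = d, volume = seq_along(d) / length(d))),
            class = "dvh")
}

#' Dose at volume (D_v)
#'
#' The dose received by at least `v`% of the ROI volume, on raw voxel
#' samples without interpolation: the (floor(N v/100) + 1)-th largest sample
#' (capped at the minimum), i.e. the largest dose exceeded by strictly more
#' than v% of the volume. D95 <= D5 always holds.
#'
#' @param x A [dvh()].
#' @param v Volume percentage in [0, 100].
#' @return Dose (GyRBE).
#' @export
d_at_volume <- function(x, v) {
  stopifnot(inherits(x, "dvh"), v >= 0, v <= 100)
  n <- length(x$samples)
  k <- min(n, floor(n * v / 100) + 1)
  x$samples[k]
}

#' Homogeneity index
#'
#' `HI = D95 / D5` for the CTV; 1 is perfectly flat.
#'
#' @param dose,roi_idx As in [dvh()].
#' @return Dimensionless HI.
#' @export
homogeneity_index <- function(dose, roi_idx) {
  h <- dvh(dose, roi_idx)
  d_at_volume(h, 95) / d_at_volume(h, 5)
}

#' Paddick conformity index
#'
#' `CI = |TV intersect PIV|^2 / (|TV| |PIV|)` where PIV is the set of scored
#' voxels receiving at least the prescription; 1 is perfect conformity.
#'
#' @param dose Dose vector over the scored voxels.
#' @param target_idx Indices of the target voxels within `dose`.
#' @param prescription Prescription dose (> 0).
#' @return CI in (0, 1]; 0 with a warning if no voxel reaches prescription.
#' @export
paddick_ci <- function(dose, target_idx, prescription) {
  stopifnot(prescription > 0)
  piv <- dose >= prescription
  n_piv <- sum(piv)
  if (n_piv == 0) {
    warning("no voxel reaches the prescription dose; CI = 0")
    return(0)
  }
  overlap <- sum(piv[target_idx])
  overlap^2 / (length(target_idx) * n_piv)
}

#' The 28-scenario robustness evaluation set
#'
#' 14 setup-shift directions of 3 mm norm (6 axial and 8 body-diagonal,
#' diagonals normalized to 0.3 cm) crossed with SPR scales 0.965 and 1.035
#' (3.5% density uncertainty): exactly 28 scenarios, no nominal member.
#'
#' @param shift Shift norm in cm (default 0.3).
#' @param spr_err Relative SPR error (default 0.035).
#' @return List of 28 [make_scenario()] objects.
#' @export
evaluation_scenarios <- function(shift = 0.3, spr_err = 0.035) {
  dirs <- rbind(diag(3), -diag(3),
                as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1))) /
                  sqrt(3))
  out <- list()
  for (i in seq_len(nrow(dirs))) {
    for (s in c(1 - spr_err, 1 + spr_err)) {
      out[[length(out) + 1]] <- make_scenario(
        shift = dirs[i, ] * shift, spr_scale = s,
        label = sprintf("eval_%02d_%s", i,
                        if (s < 1) "minus" else "plus"))
    }
  }
  out
}

#' Worst-case CTV D95 over the evaluation scenarios
#'
#' Recomputes the CTV dose under each of the 28 perturbation scenarios and
#' returns the minimum D95 as a percentage of the prescription.
#'
#' @param phantom,plan,bm Geometry, optimized plan and beam model.
#' @param weights Spot MU vector (default the plan's).
#' @param scenarios Scenario list, default [evaluation_scenarios()].
#' @return List with `worst_case_d95_pct` and the per-scenario tibble.
#' @export
worst_case_d95 <- function(phantom, plan, bm, weights = plan$spots$mu,
                           scenarios = evaluation_scenarios()) {
  ctv_idx <- which(phantom$rois[[phantom$target]])
  vals <- vapply(scenarios, function(sc) {
    infl <- influence_matrix(phantom$grid, plan, bm, sc, rows = ctv_idx)
    d <- as.numeric(infl %*% weights)
    d_at_volume(dvh(d, seq_along(d), phantom$target), 95)
  }, numeric(1))
  tibble::tibble(
    label = vapply(scenarios, `[[`, character(1), "label"),
    d95 = vals,
    d95_pct = vals / plan$prescription * 100
  ) -> per_scenario
  list(worst_case_d95_pct = min(per_scenario$d95_pct),
       per_scenario = per_scenario)
}

#' Shoot-through fraction and proton totals
#'
#' The percentage of irradiated protons delivered by shoot-through spots
#' (MU is proportional to protons, so the MU fraction equals the proton
#' fraction) and the total proton count of the plan.
#'
#' @param plan An `arc_plan` with optimized weights.
#' @param bm A [beam_model()].
#' @return `st_fraction`: percent in [0, 100]; `total_protons`: count.
#' @export
st_fraction <- function(plan) {
  tot <- sum(plan$spots$mu)
  if (tot == 0) return(0)
  sum(plan$spots$mu[plan$spots$is_st]) / tot * 100
}

#' @rdname st_fraction
#' @export
total_protons <- function(plan, bm = beam_model_constants()) {
  mu_to_protons(sum(plan$spots$mu), bm)
}

#' Plan-quality metrics
#'
#' One-row tibble mirroring the study's reporting columns: active energy
#' layers and spots, shoot-through percentage, total protons, delivery time,
#' Paddick CI, HI (D95/D5), worst-case CTV D95 over the 28-scenario
#' robustness evaluation, and mean External dose.
#'
#' @param phantom,plan,bm Geometry, optimized plan and beam model.
#' @param infl_nom Optional cached nominal influence matrix over the External
#'   voxels (recomputed if missing).
#' @param time_model A [time_model()].
#' @param robustness Run the 28-scenario evaluation? (Somewhat costly.)
#' @return A one-row tibble of class `plan_metrics`.
#' @export
plan_metrics <- function(phantom, plan, bm, infl_nom = NULL,
                         time_model = starc::time_model(),
                         robustness = TRUE) {
  ext_idx <- which(phantom$rois$External)
  if (is.null(infl_nom)) {
    infl_nom <- influence_matrix(phantom$grid, plan, bm, rows = ext_idx)
  }
  w <- plan$spots$mu
  d <- as.numeric(infl_nom %*% w)
  ctv_pos <- match(which(phantom$rois[[phantom$target]]), ext_idx)
  active <- w > 0
  tb <- plan_time(plan, time_model)
  wc <- if (robustness) {
    worst_case_d95(phantom, plan, bm)$worst_case_d95_pct
  } else NA_real_
  out <- tibble::tibble(
    n_layers = length(unique(plan$spots$layer_id[active])),
    n_spots = sum(active),
    st_pct = st_fraction(plan),
    total_protons = total_protons(plan, bm),
    delivery_time_s = tb$total,
    ci = paddick_ci(d, ctv_pos, plan$prescription),
    hi = homogeneity_index(d, ctv_pos),
    worst_case_d95_pct = wc,
    external_mean = mean(d)
  )
  class(out) <- c("plan_metrics", class(out))
  out
}

#' @method autoplot dvh
#' @export
autoplot.dvh <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(.data$dose, .data$volume)) +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::labs(x = "Dose (GyRBE)", y = "Volume fraction",
                  title = object$roi) +
    ggplot2::theme_minimal()
}
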
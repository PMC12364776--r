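#' Default objective set for the phantom plans
#'
#' The study's objective configuration (prescription 60 GyRBE): a uniform
#' dose objective on the CTV (weight 20), min-DVH 60 GyRBE to 95% volume
#' (weight 5), max-DVH 60 GyRBE to 2% volume (weight 10), a max-EUD (A = 1)
#' objective of 4 GyRBE on the OAR (weight 3) — all robust — and two dose
#' fall-off objectives on the External: 60 to 0 GyRBE over 1 cm (nominal
#' weight 0.5) and 60 to 10 GyRBE over 0.5 cm (nominal weight 1), whose
#' weights are scaled by `falloff_weight_factor` (1-4 sweeps the
#' conformity/homogeneity trade-off).
#'
#' @param prescription Target dose (GyRBE).
#' @param falloff_weight_factor Multiplier on the fall-off weights.
#' @return A tibble of objective terms.
#' @export
default_objectives <- function(prescription = 60, falloff_weight_factor = 1) {
  tibble::tribble(
    ~kind,      ~roi,       ~dose, ~dose_low, ~volume, ~eud_a, ~dist_l, ~weight, ~robust,
    "uniform",  "CTV",      prescription, NA,  NA,      NA,     NA,      20,      TRUE,
    "min_dvh",  "CTV",      prescription, NA,  95,      NA,     NA,      5,       TRUE,
    "max_dvh",  "CTV",      prescription, NA,  2,       NA,     NA,      10,      TRUE,
    "max_eud",  "OAR",      4,            NA,  NA,      1,      NA,      3,       TRUE,
    "falloff",  "External", prescription, 0,   NA,      NA,     1,       0.5 * falloff_weight_factor, FALSE,
    "falloff",  "External", prescription, 10,  NA,      NA,     0.5,     1 * falloff_weight_factor,   FALSE
  )
}

#' Scenario set for robust optimization
#'
#' Nominal plus six axial 3 mm setup shifts plus +/-3.5% SPR scales: nine
#' scenarios whose per-term worst case defines the robust objective value
#' (minimax). Smaller than the 28-member evaluation set, which is reserved
#' for plan evaluation.
#'
#' @param shift Setup shift magnitude (cm), default 0.3.
#' @param spr_err Relative SPR error, default 0.035.
#' @return List of [make_scenario()] objects (nominal first).
#' @export
robust_scenario_set <- function(shift = 0.3, spr_err = 0.035) {
  sc <- list(scenario_nominal())
  axes <- rbind(diag(3), -diag(3))
  for (i in seq_len(6)) {
    sc[[length(sc) + 1]] <- make_scenario(shift = axes[i, ] * shift,
                                          label = sprintf("shift_%d", i))
  }
  sc[[length(sc) + 1]] <- make_scenario(spr_scale = 1 - spr_err,
                                        label = "spr_minus")
  sc[[length(sc) + 1]] <- make_scenario(spr_scale = 1 + spr_err,
                                        label = "spr_plus")
  sc
}

#' Assemble an optimization problem
#'
#' Computes the nominal influence matrix over the patient (External) voxels
#' and, for each non-nominal robust scenario, an influence matrix restricted
#' to the voxels the robust terms act on (CTV and OAR), plus the
#' CTV-distance field the fall-off objectives need.
#'
#' @param phantom Result of [build_phantom()].
#' @param plan An `arc_plan`.
#' @param bm A [beam_model()].
#' @param objectives Objective tibble, see [default_objectives()].
#' @param scenarios Robust scenario list, see [robust_scenario_set()];
#'   `list()` disables robust terms' extra scenarios.
#' @return An `optimization_problem` list.
#' @export
optimization_problem <- function(phantom, plan, bm,
                                 objectives = default_objectives(plan$prescription),
                                 scenarios = robust_scenario_set()) {
  grid <- phantom$grid
  ext_idx <- which(phantom$rois$External)
  ctv_mask <- phantom$rois[[phantom$target]]
  oar_mask <- phantom$rois$OAR
  roi_nom <- list(
    CTV = match(which(ctv_mask), ext_idx),
    OAR = match(which(oar_mask), ext_idx),
    External = seq_along(ext_idx)
  )
  if (any(objectives$roi == "CTV") && length(roi_nom$CTV) == 0) {
    stop("CTV is empty", call. = FALSE)
  }

  # fall-off needs distance from each External voxel outside the CTV to the
  # CTV surface (distance to nearest CTV voxel centre minus half a voxel)
  shell <- setdiff(seq_along(ext_idx), roi_nom$CTV)
  ctv_pts <- voxel_centers(grid, which(ctv_mask))
  dist_ctv <- rep(0, length(ext_idx))
  dist_ctv[shell] <- pmax(
    cpp_min_dist(voxel_centers(grid, ext_idx[shell]), ctv_pts) -
      grid$spacing / 2, 0)

  rob_idx <- sort(union(which(ctv_mask), which(oar_mask)))
  roi_rob <- list(
    CTV = match(which(ctv_mask), rob_idx),
    OAR = match(which(oar_mask), rob_idx)
  )

  infl_nom <- influence_matrix(grid, plan, bm, scenario_nominal(),
                               rows = ext_idx)
  extra <- scenarios[vapply(scenarios, function(s)
    s$label != "nominal", logical(1))]
  infl_rob <- lapply(extra, function(s)
    influence_matrix(grid, plan, bm, s, rows = rob_idx))

  structure(list(
    plan = plan, bm = bm, objectives = objectives,
    ext_idx = ext_idx, roi_nom = roi_nom, roi_rob = roi_rob,
    shell = shell, dist_ctv = dist_ctv,
    infl_nom = infl_nom, infl_rob = infl_rob,
    scenarios = extra,
    min_spot_mu = bm$min_spot_mu
  ), class = "optimization_problem")
}

#' Generalized equivalent uniform dose
#'
#' `EUD_A = (mean(d^A))^(1/A)`; A = 1 is the mean dose, large A approaches
#' the maximum.
#'
#' @param dose Non-negative dose samples.
#' @param A Non-zero exponent.
#' @return EUD in the dose units.
#' @export
eud <- function(dose, A) {
  if (A == 0) stop("A = 0 (geometric mean) unsupported", call. = FALSE)
  stopifnot(all(dose >= 0))
  mean(dose^A)^(1 / A)
}

# value (and residual) of one objective term on one dose vector, with the
# ROI index sets in `roi` and fall-off context in `ctx`
term_eval <- function(term, d, roi, ctx = NULL, grad = FALSE) {
  kind <- term$kind
  w <- term$weight
  if (kind == "falloff") {
    sub <- ctx$shell
    ds <- d[sub]
    dref <- pmax(term$dose_low,
                 term$dose - (term$dose - term$dose_low) *
                   ctx$dist_ctv[sub] / term$dist_l)
    ex <- pmax(0, ds - dref)
    val <- w * mean(ex^2)
    if (!grad) return(list(value = val))
    r <- numeric(length(d))
    r[sub] <- w * 2 * ex / length(sub)
    return(list(value = val, residual = r))
  }
  idx <- roi[[term$roi]]
  if (length(idx) == 0) stop("ROI '", term$roi, "' empty", call. = FALSE)
  ds <- d[idx]
  n <- length(ds)
  if (kind == "uniform") {
    val <- w * mean((ds - term$dose)^2)
    if (!grad) return(list(value = val))
    r <- numeric(length(d))
    r[idx] <- w * 2 * (ds - term$dose) / n
    return(list(value = val, residual = r))
  }
  if (kind == "max_eud") {
    e <- eud(ds, term$eud_a)
    ex <- max(0, e - term$dose)
    val <- w * ex^2
    if (!grad) return(list(value = val))
    r <- numeric(length(d))
    if (ex > 0) {
      # d EUD / d d_i for the generalized mean
      gi <- if (term$eud_a == 1) rep(1 / n, n) else
        (ds^(term$eud_a - 1)) * e^(1 - term$eud_a) / n
      r[idx] <- w * 2 * ex * gi
    }
    return(list(value = val, residual = r))
  }
  if (kind %in% c("min_dvh", "max_dvh")) {
    # "cheapest-to-fix" DVH penalty: the allowed count of voxels may stay on
    # the wrong side of the dose level; only the excess violators nearest the
    # level are penalized
    if (kind == "min_dvh") {
      n_allowed <- floor(n * (1 - term$volume / 100))
      ord <- order(ds)            # coldest first
      viol <- ds < term$dose
    } else {
      n_allowed <- floor(n * term$volume / 100)
      ord <- order(ds, decreasing = TRUE)  # hottest first
      viol <- ds > term$dose
    }
    allowed <- ord[seq_len(n_allowed)]
    pen <- setdiff(which(viol), allowed)
    if (length(pen) == 0) {
      if (!grad) return(list(value = 0))
      return(list(value = 0, residual = numeric(length(d))))
    }
    # normalized over the whole ROI (not the penalized subset) so the
    # per-voxel gradient stays continuous as the violation set changes size
    val <- w * sum((ds[pen] - term$dose)^2) / n
    if (!grad) return(list(value = val))
    r <- numeric(length(d))
    r[idx[pen]] <- w * 2 * (ds[pen] - term$dose) / n
    return(list(value = val, residual = r))
  }
  stop("unknown objective kind: ", kind, call. = FALSE)
}

#' Composite objective value
#'
#' Sum over terms of the weighted term values; robust terms take the worst
#' (largest) value over the nominal and perturbed-scenario doses.
#'
#' @param doses List with `nominal` (dose over the problem's External voxels)
#'   and `scenarios` (list of doses over the robust-ROI voxels).
#' @param problem An [optimization_problem()] (supplies terms and ROI maps).
#' @return Scalar objective value.
#' @export
objective_value <- function(doses, problem) {
  obj_eval(doses, problem, grad = FALSE)$value
}

obj_eval <- function(doses, problem, grad = FALSE) {
  terms <- problem$objectives
  ctx <- list(shell = problem$shell, dist_ctv = problem$dist_ctv)
  total <- 0
  r_nom <- numeric(length(doses$nominal))
  nsc <- length(doses$scenarios)
  r_sc <- lapply(doses$scenarios, function(d) numeric(length(d)))
  for (ti in seq_len(nrow(terms))) {
    term <- terms[ti, ]
    if (isTRUE(term$robust) && nsc > 0) {
      vals <- numeric(nsc + 1)
      vals[1] <- term_eval(term, doses$nominal, problem$roi_nom, ctx)$value
      for (s in seq_len(nsc)) {
        vals[s + 1] <- term_eval(term, doses$scenarios[[s]],
                                 problem$roi_rob, ctx)$value
      }
      worst <- which.max(vals)
      total <- total + vals[worst]
      if (grad) {
        if (worst == 1) {
          te <- term_eval(term, doses$nominal, problem$roi_nom, ctx, TRUE)
          r_nom <- r_nom + te$residual
        } else {
          te <- term_eval(term, doses$scenarios[[worst - 1]],
                          problem$roi_rob, ctx, TRUE)
          r_sc[[worst - 1]] <- r_sc[[worst - 1]] + te$residual
        }
      }
    } else {
      te <- term_eval(term, doses$nominal, problem$roi_nom, ctx, grad)
      total <- total + te$value
      if (grad) r_nom <- r_nom + te$residual
    }
  }
  if (!is.finite(total)) stop("non-finite objective value", call. = FALSE)
  out <- list(value = total)
  if (grad) {
    g <- as.numeric(Matrix::crossprod(problem$infl_nom, r_nom))
    for (s in seq_len(nsc)) {
      if (any(r_sc[[s]] != 0)) {
        g <- g + as.numeric(Matrix::crossprod(problem$infl_rob[[s]],
                                              r_sc[[s]]))
      }
    }
    out$grad <- g
  }
  out
}

# doses for a weight vector, restricted to an active-spot index set
problem_doses <- function(problem, w) {
  list(
    nominal = as.numeric(problem$infl_nom %*% w),
    scenarios = lapply(problem$infl_rob, function(m) as.numeric(m %*% w))
  )
}

# bound-constrained quasi-Newton descent (L-BFGS-B) on the active spot set;
# records the monotone sequence of accepted (improving) objective values
qn_descent <- function(problem, w0, active, lower, max_iter, tol = 1e-6) {
  idx <- which(active)
  if (length(idx) == 0) {
    return(list(w = numeric(length(w0)), history = numeric(0),
                convergence = 0L))
  }
  sub <- list(
    infl_nom = problem$infl_nom[, idx, drop = FALSE],
    infl_rob = lapply(problem$infl_rob, function(m)
      m[, idx, drop = FALSE]),
    objectives = problem$objectives,
    roi_nom = problem$roi_nom, roi_rob = problem$roi_rob,
    shell = problem$shell, dist_ctv = problem$dist_ctv
  )
  hist <- numeric(0)
  best <- Inf
  cache <- new.env(parent = emptyenv())
  evaluate <- function(x) {
    key <- identical(cache$x, x)
    if (!key) {
      cache$x <- x
      cache$ev <- obj_eval(list(
        nominal = as.numeric(sub$infl_nom %*% x),
        scenarios = lapply(sub$infl_rob, function(m) as.numeric(m %*% x))
      ), sub, grad = TRUE)
      if (cache$ev$value < best) {
        best <<- cache$ev$value
        hist <<- c(hist, best)
      }
    }
    cache$ev
  }
  factr <- max(tol / .Machine$double.eps / 1e3, 1e7)
  opt <- stats::optim(
    w0[idx], fn = function(x) evaluate(x)$value,
    gr = function(x) evaluate(x)$grad,
    method = "L-BFGS-B", lower = lower[idx],
    control = list(maxit = max_iter, factr = factr))
  w <- numeric(length(w0))
  w[idx] <- opt$par
  list(w = w, history = hist, convergence = opt$convergence)
}

#' Optimize spot weights
#'
#' Two-phase robust spot-weight optimization with energy-layer and
#' minimum-MU spot filtering:
#' phase 1 optimizes all spots (non-negative weights, monotone projected
#' gradient with Barzilai-Borwein steps); [filter_layers()] then keeps the
#' `final_layers` Bragg layers with the largest total MU (shoot-through
#' layers are exempt, each direction keeps at least one Bragg layer);
#' [filter_spots()] removes spots below the 0.0683 MU deliverability floor;
#' phase 2 re-optimizes the survivors; finally sub-floor stragglers are
#' removed and the remainder re-optimized with the floor as a hard lower
#' bound (clipping-with-reoptimization, started from the naively clipped
#' point so the final objective can only improve on naive clipping). Fully
#' deterministic: the initial weights are uniform at twice the floor.
#'
#' @param problem An [optimization_problem()].
#' @param final_layers Bragg-layer budget after filtering (the 480 to 240
#'   default scales with the initial request); `Inf` disables.
#' @param max_iter Iteration cap per phase.
#' @param tol Relative objective-stall tolerance.
#' @return An `optimization_result` with `weights` (MU per spot), per-phase
#'   `history`, the filtered `plan`, and spot/layer counts per phase.
#' @export
optimize_weights <- function(problem, final_layers = Inf, max_iter = 200,
                             tol = 1e-6) {
  plan <- problem$plan
  nspot <- nrow(plan$spots)
  floor_mu <- problem$min_spot_mu
  # deterministic warm start: uniform weights at twice the floor, scaled so
  # the nominal CTV mean dose matches the prescription
  w0 <- rep(2 * floor_mu, nspot)
  d0 <- as.numeric(problem$infl_nom %*% w0)
  presc <- plan$prescription %||% 60
  m0 <- mean(d0[problem$roi_nom$CTV])
  if (m0 > 0) w0 <- w0 * presc / m0
  active <- rep(TRUE, nspot)
  zero <- numeric(nspot)
  counts <- list(initial = c(layers = nrow(plan$layers), spots = nspot))

  ph1 <- qn_descent(problem, w0, active, zero, max_iter, tol)
  keep_layers <- filter_layers(plan, ph1$w, final_layers)
  active <- plan$spots$layer_id %in% keep_layers
  w <- ph1$w
  w[!active] <- 0
  active <- active & filter_spots(w, floor_mu)
  w[!active] <- 0
  counts$after_filter <- c(layers = length(keep_layers),
                           spots = sum(active))

  ph2 <- qn_descent(problem, w, active, zero, max_iter, tol)
  # clipping-with-reoptimization: drop sub-floor spots, clip the rest up to
  # the floor, then descend with the floor as lower bound
  active <- active & filter_spots(ph2$w, floor_mu)
  w <- ph2$w
  w[!active] <- 0
  w[active] <- pmax(w[active], floor_mu)
  ph3 <- qn_descent(problem, w, active, ifelse(active, floor_mu, 0),
                    ceiling(max_iter / 4), tol)
  w <- ph3$w
  w[!active] <- 0
  counts$final <- c(layers = length(unique(
    plan$spots$layer_id[active & w > 0])), spots = sum(w > 0))

  plan$spots$mu <- w
  structure(list(
    weights = w, plan = plan,
    history = list(phase1 = ph1$history, phase2 = ph2$history,
                   phase3 = ph3$history),
    counts = counts, kept_layers = keep_layers
  ), class = "optimization_result")
}

#' Energy-layer filtering
#'
#' Keeps the `final_count` Bragg layers with the largest total MU;
#' shoot-through layers are structural and exempt; ties broken toward lower
#' energy; every direction keeps at least its strongest Bragg layer when it
#' has one.
#'
#' @param plan An `arc_plan`.
#' @param weights Current spot MU vector.
#' @param final_count Bragg layers to keep.
#' @return Integer vector of kept `layer_id`s (Bragg and ST).
#' @export
filter_layers <- function(plan, weights, final_count) {
  lay <- plan$layers
  mu_by_layer <- tapply(weights, plan$spots$layer_id, sum)
  lay$total_mu <- as.numeric(mu_by_layer[as.character(lay$layer_id)])
  lay$total_mu[is.na(lay$total_mu)] <- 0
  bragg <- lay[!lay$is_st, ]
  st_ids <- lay$layer_id[lay$is_st]
  if (!is.finite(final_count) || final_count >= nrow(bragg)) {
    return(c(bragg$layer_id, st_ids))
  }
  bragg <- bragg[order(-bragg$total_mu, bragg$energy), ]
  # per-direction floor: strongest Bragg layer of each direction survives
  forced <- bragg$layer_id[!duplicated(bragg$dir_index)]
  n_more <- max(final_count - length(forced), 0)
  rest <- setdiff(bragg$layer_id, forced)
  kept <- c(forced, rest[seq_len(min(n_more, length(rest)))])
  c(sort(kept), st_ids)
}

#' Minimum-MU spot filter
#'
#' Logical mask of spots at or above the deliverability floor (0.0683 MU);
#' spots below it are removed from the plan (weight zeroed, excluded from
#' re-optimization).
#'
#' @param weights Spot MU vector.
#' @param min_mu Floor in MU.
#' @return Logical vector, `TRUE` for surviving spots.
#' @export
filter_spots <- function(weights, min_mu = 0.0683) {
  weights >= min_mu - 1e-12
}

#' @export
print.optimization_result <- function(x, ...) {
  cat("<optimization_result> ", x$counts$final["spots"], " active spots in ",
      x$counts$final["layers"], " layers; objective ",
      format(utils::tail(x$history$phase3, 1)), "\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @method tidy optimization_result
#' @export
tidy.optimization_result <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(phase = "phase1", iteration = seq_along(x$history$phase1),
                   objective = x$history$phase1),
    tibble::tibble(phase = "phase2", iteration = seq_along(x$history$phase2),
                   objective = x$history$phase2),
    tibble::tibble(phase = "phase3", iteration = seq_along(x$history$phase3),
                   objective = x$history$phase3)
  )
}

#' @importFrom generics glance
#' @method glance optimization_result
#' @export
glance.optimization_result <- function(x, ...) {
  tibble::tibble(
    n_spots = unname(x$counts$final["spots"]),
    n_layers = unname(x$counts$final["layers"]),
    objective = utils::tail(x$history$phase3, 1),
    total_mu = sum(x$weights)
  )
}
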
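#' Perturbation scenario
#'
#' A geometry perturbation used for robust optimization, robustness
#' evaluation and range verification: a rigid setup shift (applied as a
#' translation of the beam geometry relative to the patient grid, which is
#' equivalent to the rigid patient shift but avoids resampling artefacts), a
#' global SPR/density scale, and optionally a named sub-volume displacement.
#'
#' @param shift Length-3 setup shift in cm (patient displacement).
#' @param spr_scale Global SPR factor (1.0 nominal; 3.5% density error =
#'   0.965/1.035).
#' @param label Scenario label.
#' @param displacement Optional list(region = mask, vector = cm shift) for
#'   localized anatomy change.
#' @return A `scenario` list. `scenario_nominal()` is the identity.
#' @export
make_scenario <- function(shift = c(0, 0, 0), spr_scale = 1,
                          label = "scenario", displacement = NULL) {
  stopifnot(length(shift) == 3, spr_scale > 0)
  structure(list(shift = as.numeric(shift), spr_scale = spr_scale,
                 label = label, displacement = displacement),
            class = "scenario")
}

#' @rdname make_scenario
#' @export
scenario_nominal <- function() make_scenario(label = "nominal")

# apply a scenario's SPR-side perturbations to a grid (shift handled beam-side)
scenario_grid <- function(grid, scenario) {
  g <- grid
  if (!is.null(scenario$displacement)) {
    g <- displace_subvolume(g, scenario$displacement$region,
                            scenario$displacement$vector)
  }
  if (scenario$spr_scale != 1) g <- scale_spr(g, scenario$spr_scale)
  g
}

#' Water-equivalent thickness along a ray
#'
#' Exact voxel-walking (Siddon) traversal: the sum over traversed voxels of
#' chord length times voxel SPR. Vectorized over rays.
#'
#' @param grid A [spr_grid()].
#' @param origin n x 3 matrix (or length-3 vector) of ray start points (cm).
#' @param direction n x 3 matrix (or length-3 vector) of unit directions.
#' @param length Maximum traversal length (cm), default unbounded.
#' @return Numeric vector of WET values (cm).
#' @export
wet_along_ray <- function(grid, origin, direction, length = Inf) {
  stopifnot(inherits(grid, "spr_grid"))
  if (is.null(dim(origin))) origin <- matrix(origin, ncol = 3)
  if (is.null(dim(direction))) direction <- matrix(direction, ncol = 3)
  nrm <- sqrt(rowSums(direction^2))
  if (any(nrm < 1e-12)) stop("zero direction vector", call. = FALSE)
  direction <- direction / nrm
  if (base::length(length) == 1) length <- rep(length, nrow(origin))
  cpp_wet_rays(grid$spr, grid$shape, grid$spacing, grid$origin,
               origin, direction, length)
}

#' Aperture transmission at a lateral point
#'
#' 1 deep inside the contour, 0 far outside, with a smooth error-function
#' edge of width `edge_sigma` (0.5 on the boundary).
#'
#' @param u,v BEV coordinates (cm) of the query points.
#' @param aperture An `aperture` from [make_aperture()].
#' @return Transmission in [0, 1].
#' @export
aperture_transmission <- function(u, v, aperture) {
  gu <- (u - aperture$umin) / aperture$h + 1
  gv <- (v - aperture$vmin) / aperture$h + 1
  iu <- pmin(pmax(floor(gu), 1), aperture$nu - 1)
  iv <- pmin(pmax(floor(gv), 1), aperture$nv - 1)
  fu <- pmin(pmax(gu - iu, 0), 1)
  fv <- pmin(pmax(gv - iv, 0), 1)
  tr <- aperture$trans
  out <- (1 - fu) * (1 - fv) * tr[cbind(iu, iv)] +
    fu * (1 - fv) * tr[cbind(iu + 1, iv)] +
    (1 - fu) * fv * tr[cbind(iu, iv + 1)] +
    fu * fv * tr[cbind(iu + 1, iv + 1)]
  out[u < aperture$umin | v < aperture$vmin |
        u > aperture$umin + (aperture$nu - 1) * aperture$h |
        v > aperture$vmin + (aperture$nv - 1) * aperture$h] <- 0
  out
}

# distance upstream of the isocenter where parallel rays start
SOURCE_DIST <- 40

#' Dose influence matrix
#'
#' Sparse matrix of dose (GyRBE) per unit MU for (voxel, spot) pairs under a
#' scenario. Each spot deposits an analytic pencil-beam kernel: depth-dose at
#' the voxel's water-equivalent depth along the spot's central axis, a lateral
#' Gaussian of depth-dependent sigma, aperture edge-truncation for collimated
#' plans, times RBE 1.1 and the machine calibration. Setup shifts translate
#' the beam geometry; density scales multiply the SPR before the WED
#' ray-trace. Kernels are cut off at 3.5 lateral sigma and beyond the
#' depth-dose support.
#'
#' @param grid A [spr_grid()] (nominal geometry).
#' @param plan An `arc_plan`.
#' @param bm A [beam_model()].
#' @param scenario A [make_scenario()]; default nominal.
#' @param rows Integer vector of 1-based linear voxel indices to score
#'   (typically the External mask: dose is scored in the patient). Default
#'   all voxels.
#' @return A `Matrix::dgCMatrix` (length(rows) x n_spots) with attributes
#'   `rows`, `scenario`.
#' @export
influence_matrix <- function(grid, plan, bm, scenario = scenario_nominal(),
                             rows = NULL) {
  stopifnot(inherits(plan, "arc_plan"))
  if (is.null(rows)) rows <- seq_len(prod(grid$shape))
  g <- scenario_grid(grid, scenario)
  vox <- voxel_centers(g, rows)
  iso <- -scenario$shift  # patient shifted +s == beam at -s in patient frame

  et <- bm$energy_table
  # depth-dose curves on a shared z grid
  zmax <- max(et$range) + 4 * sigma_range(max(et$range), bm)
  dd_z <- seq(0, zmax, by = 0.02)
  energies <- sort(unique(plan$spots$energy))
  dd_val <- matrix(0, nrow = length(energies), ncol = length(dd_z))
  for (i in seq_along(energies)) {
    cur <- dd_curve_cached(energies[i], bm)
    dd_val[i, ] <- stats::approx(cur$z, cur$dose, dd_z, yleft = cur$dose[1],
                                 yright = 0, rule = 2)$y
    dd_val[i, dd_z > max(cur$z)] <- 0
  }

  sp <- plan$spots
  trip_i <- list(); trip_j <- list(); trip_x <- list()
  for (di in seq_along(plan$angles)) {
    fr <- beam_frame(plan$angles[di])
    sel <- which(sp$dir_index == di)
    if (length(sel) == 0) next
    s2 <- sp[sel, ]
    dd_index <- match(s2$energy, energies) - 1L
    spot_R <- range_in_water(s2$energy, bm)
    sig_air <- sigma_air(s2$energy, bm)
    if (plan$collimated && !is.null(plan$apertures)) {
      lay_ids <- as.character(s2$layer_id)
      uniq <- unique(lay_ids)
      aps <- lapply(plan$apertures[uniq], function(a) {
        list(umin = a$umin, vmin = a$vmin, h = a$h, nu = a$nu, nv = a$nv,
             trans = as.numeric(a$trans))
      })
      aper_index <- match(lay_ids, uniq) - 1L
    } else {
      aps <- list()
      aper_index <- rep(-1L, nrow(s2))
    }
    tr <- cpp_dose_direction(
      g$spr, g$shape, g$spacing, g$origin, vox,
      fr$d, fr$u, fr$v, iso,
      cbind(s2$u, s2$v), dd_index, spot_R, sig_air,
      dd_z, dd_val, aper_index, aps,
      bm$sigma_mcs_coef, bm$cutoff_sigma, bm$calib, bm$rbe, SOURCE_DIST)
    trip_i[[di]] <- tr$i + 1L
    trip_j[[di]] <- sel[tr$j + 1L]
    trip_x[[di]] <- tr$x
  }
  m <- Matrix::sparseMatrix(
    i = unlist(trip_i), j = unlist(trip_j), x = unlist(trip_x),
    dims = c(length(rows), nrow(sp)))
  attr(m, "rows") <- rows
  attr(m, "scenario") <- scenario$label
  m
}

#' Dose distribution of a plan
#'
#' @param infl Influence matrix from [influence_matrix()].
#' @param weights Spot MU vector; default the plan weights used to build it.
#' @return Numeric dose vector (GyRBE) over the scored voxels.
#' @export
plan_dose <- function(infl, weights) {
  as.numeric(infl %*% weights)
}

#' Dose of a single spot on the full grid
#'
#' Convenience wrapper computing one spot's dose contribution (per its MU).
#'
#' @param grid A [spr_grid()].
#' @param plan An `arc_plan` (for geometry/apertures).
#' @param spot_id Spot to compute.
#' @param bm A [beam_model()].
#' @param scenario Optional scenario.
#' @return Numeric vector of dose (GyRBE) per grid voxel.
#' @export
spot_dose <- function(grid, plan, spot_id, bm,
                      scenario = scenario_nominal()) {
  sub <- plan
  sub$spots <- plan$spots[plan$spots$spot_id == spot_id, ]
  stopifnot(nrow(sub$spots) == 1)
  infl <- influence_matrix(grid, sub, bm, scenario)
  as.numeric(infl[, 1]) * sub$spots$mu[1]
}
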
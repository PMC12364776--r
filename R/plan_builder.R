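#' Arc directions
#'
#' `n` beam azimuths in the patient axial plane, spacing 360/n starting at 0
#' (0 deg = beam entering from anterior, increasing clockwise viewed from
#' superior). All arc plans in the study use 20 uniformly spaced directions.
#'
#' @param n Number of directions (>= 1).
#' @param full_arc Kept for symmetry with fixed-beam plans; uniform full-arc
#'   spacing is always produced.
#' @return Numeric vector of angles in degrees.
#' @export
make_arc_directions <- function(n = 20, full_arc = TRUE) {
  stopifnot(n >= 1)
  seq(0, by = 360 / n, length.out = n)
}

# Beam frame for an azimuth (degrees): unit beam axis d (direction of travel),
# BEV lateral u-hat (axial plane) and v-hat (= +z). Parallel-beam geometry.
beam_frame <- function(angle) {
  th <- angle * pi / 180
  d <- c(-sin(th), -cos(th), 0)
  u <- c(-d[2], d[1], 0)
  list(d = d, u = u, v = c(0, 0, 1))
}

# WED (cm) of target voxels along a direction: distance-weighted SPR from the
# grid boundary to each voxel centre, traced backwards along the beam axis.
target_wed <- function(grid, target, angle) {
  idx <- which(target)
  if (length(idx) == 0) stop("target projection empty", call. = FALSE)
  fr <- beam_frame(angle)
  pts <- voxel_centers(grid, idx)
  dirs <- matrix(rep(-fr$d, each = length(idx)), ncol = 3)
  wed <- cpp_wet_rays(grid$spr, grid$shape, grid$spacing, grid$origin,
                      pts, dirs, rep(Inf, length(idx)))
  list(idx = idx, wed = wed, frame = fr, pts = pts)
}

#' Select energy layers for one direction
#'
#' Machine energies whose ranges sample the target's water-equivalent-depth
#' interval `[WETmin - sigma_R, WETmax + sigma_R]` along the direction,
#' uniformly in range, snapped to the deliverable table and deduplicated. The
#' requested count is the per-direction share of the plan's initial layer
#' budget (e.g. 480 layers over 20 directions = 24 requested each).
#'
#' @param grid A [spr_grid()].
#' @param target Logical CTV mask.
#' @param angle Beam azimuth (degrees).
#' @param n_layers Requested number of layers (>= 1).
#' @param bm A [beam_model()].
#' @return Tibble with `energy` and `range` of the selected layers.
#' @export
select_energy_layers <- function(grid, target, angle, n_layers, bm) {
  stopifnot(n_layers >= 1)
  tw <- target_wed(grid, target, angle)
  sr <- sigma_range(max(tw$wed), bm)
  r_lo <- max(min(tw$wed) - sr, min(bm$energy_table$range))
  r_hi <- min(max(tw$wed) + sr, max(bm$energy_table$range))
  want <- if (n_layers == 1) (r_lo + r_hi) / 2 else
    seq(r_lo, r_hi, length.out = n_layers)
  pick <- vapply(want, function(r) which.min(abs(bm$energy_table$range - r)),
                 integer(1))
  pick <- sort(unique(pick))
  bm$energy_table[pick, c("energy", "range")]
}

# Lattice positions (u, v) covering a set of BEV points dilated by `margin`.
# Rectangular lattice anchored at the patient origin, spacing `spot_spacing`.
spot_lattice <- function(uv, margin, spot_spacing) {
  if (nrow(uv) == 0) return(matrix(numeric(0), ncol = 2))
  ulim <- range(uv[, 1]) + c(-1, 1) * margin
  vlim <- range(uv[, 2]) + c(-1, 1) * margin
  ug <- seq(floor(ulim[1] / spot_spacing), ceiling(ulim[2] / spot_spacing)) *
    spot_spacing
  vg <- seq(floor(vlim[1] / spot_spacing), ceiling(vlim[2] / spot_spacing)) *
    spot_spacing
  cand <- as.matrix(expand.grid(u = ug, v = vg))
  if (nrow(cand) == 0) return(matrix(numeric(0), ncol = 2))
  dmin <- cpp_min_dist(cbind(cand, 0), cbind(uv, 0))
  cand[dmin <= margin + 1e-9, , drop = FALSE]
}

#' Place spots for one energy layer
#'
#' Rectangular spot lattice covering the beam's-eye-view projection of the
#' layer's target sub-volume, dilated by `margin_factor * sigma_air(energy)`
#' (the lateral target margin is the spot size times a configurable factor:
#' 1.0 for uncollimated plans, 1.0/1.25/1.5 explored for collimated ones).
#'
#' @param grid,target,angle Geometry as in [select_energy_layers()].
#' @param energy Layer energy (MeV).
#' @param margin_factor Margin in units of the entrance spot sigma.
#' @param spot_spacing Lattice pitch (cm), default 0.6.
#' @param wed_window Optional range window (cm); only target voxels whose WED
#'   lies within it contribute to the projection (the layer's WET slab).
#'   `NULL` uses the full target (shoot-through layers).
#' @param bm A [beam_model()].
#' @return Matrix of spot positions (u, v) in cm; may have zero rows.
#' @export
place_spots <- function(grid, target, angle, energy, margin_factor = 1,
                        spot_spacing = 0.6, wed_window = NULL,
                        bm = beam_model_constants()) {
  stopifnot(spot_spacing > 0)
  tw <- target_wed(grid, target, angle)
  keep <- if (is.null(wed_window)) rep(TRUE, length(tw$idx)) else
    tw$wed >= wed_window[1] & tw$wed < wed_window[2]
  if (!any(keep)) return(matrix(numeric(0), ncol = 2,
                                dimnames = list(NULL, c("u", "v"))))
  pts <- tw$pts[keep, , drop = FALSE]
  ctr <- sweep(pts, 2, c(0, 0, 0))
  uv <- cbind(ctr %*% tw$frame$u, ctr %*% tw$frame$v)
  margin <- margin_factor * sigma_air(energy, bm)
  out <- spot_lattice(uv, margin, spot_spacing)
  colnames(out) <- c("u", "v")
  out
}

#' Build a static-arc (or fixed-beam) plan skeleton
#'
#' Assembles directions, Bragg energy layers (WET-slab spot grids) and
#' optional per-layer apertures into an `arc_plan`. Spots start at a uniform
#' weight of twice the minimum spot MU; optimization reassigns them.
#'
#' @param phantom Result of [build_phantom()].
#' @param bm A [beam_model()].
#' @param angles Beam azimuths (degrees); default a 20-direction full arc.
#' @param n_layers_per_direction Requested initial Bragg layers per direction
#'   (the 480-layer default over 20 directions).
#' @param margin_factor Lateral margin factor (1.0 uncollimated, 1.25 default
#'   for collimated plans).
#' @param collimated Build per-layer apertures?
#' @param spot_spacing Spot lattice pitch (cm).
#' @param prescription,fractions Prescription dose (GyRBE) and fraction count.
#' @return An `arc_plan`: list with `spots` (tibble: spot_id, layer_id,
#'   dir_index, angle, energy, u, v, mu, is_st), `layers` (tibble), `angles`,
#'   `apertures`, and metadata.
#' @export
build_plan <- function(phantom, bm, angles = make_arc_directions(20),
                       n_layers_per_direction = 24, margin_factor = 1,
                       collimated = FALSE, spot_spacing = 0.6,
                       prescription = 60, fractions = 30) {
  stopifnot(!is.unsorted(angles), !anyDuplicated(angles))
  grid <- phantom$grid
  target <- phantom$rois[[phantom$target]]
  layers <- list()
  spots <- list()
  lid <- 0L
  for (di in seq_along(angles)) {
    ang <- angles[di]
    sel <- select_energy_layers(grid, target, ang, n_layers_per_direction, bm)
    # half the inter-layer range spacing defines each layer's WET slab
    rr <- sel$range
    halfgap <- if (length(rr) > 1) diff(rr) / 2 else max(sigma_range(rr, bm), 0.5)
    lo <- rr - c(halfgap[1], halfgap)[seq_along(rr)]
    hi <- rr + c(halfgap, halfgap[length(halfgap)])[seq_along(rr)]
    for (li in seq_along(rr)) {
      pos <- place_spots(grid, target, ang, sel$energy[li], margin_factor,
                         spot_spacing, wed_window = c(lo[li], hi[li]), bm = bm)
      if (nrow(pos) == 0) next
      lid <- lid + 1L
      layers[[lid]] <- tibble::tibble(
        layer_id = lid, dir_index = di, angle = ang,
        energy = sel$energy[li], is_st = FALSE,
        wed_lo = lo[li], wed_hi = hi[li])
      spots[[lid]] <- tibble::tibble(
        layer_id = lid, dir_index = di, angle = ang,
        energy = sel$energy[li], u = pos[, 1], v = pos[, 2],
        mu = 2 * bm$min_spot_mu, is_st = FALSE)
    }
  }
  plan <- structure(list(
    spots = dplyr::mutate(dplyr::bind_rows(spots),
                          spot_id = dplyr::row_number(), .before = 1),
    layers = dplyr::bind_rows(layers),
    angles = angles,
    collimated = isTRUE(collimated),
    margin_factor = margin_factor,
    spot_spacing = spot_spacing,
    prescription = prescription,
    fractions = fractions,
    apertures = NULL
  ), class = "arc_plan")
  if (collimated) plan <- add_apertures(plan, phantom, bm)
  plan
}

#' Add one shoot-through layer per direction
#'
#' Appends, for each direction, a layer at the machine's highest energy
#' (230 MeV) whose spots cover the full target projection including margins
#' (all WET slabs merged), flagged `is_st`. ST spots share the Bragg-spot
#' lattice.
#'
#' @param plan An `arc_plan`.
#' @param phantom The phantom the plan was built on.
#' @param bm A [beam_model()].
#' @param directions Direction indices to augment; default all.
#' @return The augmented plan.
#' @export
add_st_layer <- function(plan, phantom, bm, directions = NULL) {
  stopifnot(inherits(plan, "arc_plan"))
  if (is.null(directions)) directions <- seq_along(plan$angles)
  if (any(plan$layers$is_st[plan$layers$dir_index %in% directions])) {
    stop("direction already has a shoot-through layer", call. = FALSE)
  }
  grid <- phantom$grid
  target <- phantom$rois[[phantom$target]]
  newlay <- list(); newspots <- list()
  lid <- max(plan$layers$layer_id)
  for (di in directions) {
    ang <- plan$angles[di]
    pos <- place_spots(grid, target, ang, bm$e_max, plan$margin_factor,
                       plan$spot_spacing, wed_window = NULL, bm = bm)
    lid <- lid + 1L
    newlay[[length(newlay) + 1]] <- tibble::tibble(
      layer_id = lid, dir_index = di, angle = ang, energy = bm$e_max,
      is_st = TRUE, wed_lo = 0, wed_hi = Inf)
    newspots[[length(newspots) + 1]] <- tibble::tibble(
      layer_id = lid, dir_index = di, angle = ang, energy = bm$e_max,
      u = pos[, 1], v = pos[, 2], mu = 2 * bm$min_spot_mu, is_st = TRUE)
  }
  plan$layers <- dplyr::bind_rows(plan$layers, dplyr::bind_rows(newlay))
  plan$spots <- dplyr::bind_rows(plan$spots, dplyr::bind_rows(newspots))
  plan$spots$spot_id <- seq_len(nrow(plan$spots))
  if (plan$collimated) plan <- add_apertures(plan, phantom, bm)
  plan
}

#' Per-layer aperture (layer-by-layer collimation)
#'
#' The aperture contour of a layer is the beam's-eye-view projection of the
#' layer's target sub-volume dilated by the lateral margin; dose kernels are
#' edge-truncated at this contour with a smooth error-function edge. The
#' contour is the margin isoline of the distance to the projection point
#' cloud (each projected voxel carries a footprint radius `r_fill`), which
#' is the exact signed distance near the contour; transmission saturates to
#' exactly 1 deep inside. Stored on a fine BEV lattice together with the
#' boundary points the delivery-time model uses for leaf travel. Non-convex
#' layer projections (e.g. the mid-depth slabs of an H-shaped target) yield
#' non-convex contours.
#'
#' @param points Matrix/data frame with `u`, `v` columns (cm): the layer's
#'   projected sub-target (or spot) positions.
#' @param margin Dilation margin (cm) beyond the point footprints.
#' @param edge_sigma Error-function edge width (cm).
#' @param res BEV lattice resolution (cm).
#' @param r_fill Footprint radius (cm) of each projection point (half the
#'   voxel size for voxel clouds; 0 for exact point dilation).
#' @return A list (`umin`, `vmin`, `h`, `nu`, `nv`, `mask`, `trans`,
#'   `boundary`) of class `aperture`.
#' @export
make_aperture <- function(points, margin, edge_sigma = 0.1, res = 0.1,
                          r_fill = 0) {
  points <- as.data.frame(points)
  u <- points$u %||% points[, 1]
  v <- points$v %||% points[, 2]
  reach <- margin + r_fill
  pad <- reach + 4 * edge_sigma + 2 * res
  umin <- min(u) - pad
  vmin <- min(v) - pad
  ug <- seq(umin, max(u) + pad, by = res)
  vg <- seq(vmin, max(v) + pad, by = res)
  gp <- as.matrix(expand.grid(u = ug, v = vg))
  dmin <- cpp_min_dist(cbind(gp, 0), cbind(u, v, 0))
  phi <- matrix(reach - dmin, nrow = length(ug))  # signed dist near contour
  mask <- phi >= 0
  trans <- stats::pnorm(phi / edge_sigma)
  # saturate deep inside: phi underestimates the distance to the contour in
  # the scalloped interior of the point cloud, so clamp well-eroded cells
  deep <- erode2d(erode2d(erode2d(mask)))
  trans[deep] <- 1
  bnd <- mask & !erode2d(mask)
  bnd_pts <- gp[as.vector(bnd), , drop = FALSE]
  if (nrow(bnd_pts) == 0) bnd_pts <- gp[which.min(dmin), , drop = FALSE]
  structure(list(umin = umin, vmin = vmin, h = res,
                 nu = length(ug), nv = length(vg),
                 mask = mask, trans = trans, boundary = bnd_pts),
            class = "aperture")
}

# 4-neighbour binary erosion of a 2-D logical matrix
erode2d <- function(m) {
  n <- dim(m)
  out <- m
  out[1, ] <- FALSE; out[n[1], ] <- FALSE
  out[, 1] <- FALSE; out[, n[2]] <- FALSE
  inner <- m[2:(n[1] - 1), 2:(n[2] - 1)] &
    m[1:(n[1] - 2), 2:(n[2] - 1)] & m[3:n[1], 2:(n[2] - 1)] &
    m[2:(n[1] - 1), 1:(n[2] - 2)] & m[2:(n[1] - 1), 3:n[2]]
  out[2:(n[1] - 1), 2:(n[2] - 1)] <- inner
  out
}

# build/refresh apertures for all layers of a collimated plan: each layer's
# contour is its WET-slab projection dilated by the layer margin
add_apertures <- function(plan, phantom, bm) {
  grid <- phantom$grid
  target <- phantom$rois[[phantom$target]]
  aps <- vector("list", nrow(plan$layers))
  for (di in seq_along(plan$angles)) {
    tw <- target_wed(grid, target, plan$angles[di])
    uv <- cbind(tw$pts %*% tw$frame$u, tw$pts %*% tw$frame$v)
    rows <- which(plan$layers$dir_index == di)
    for (r in rows) {
      lay <- plan$layers[r, ]
      keep <- tw$wed >= lay$wed_lo & tw$wed < lay$wed_hi
      cloud <- if (any(keep)) uv[keep, , drop = FALSE] else {
        ls <- plan$spots[plan$spots$layer_id == lay$layer_id, ]
        cbind(ls$u, ls$v)
      }
      colnames(cloud) <- c("u", "v")
      margin <- plan$margin_factor * sigma_air(lay$energy, bm)
      aps[[r]] <- make_aperture(cloud, margin, bm$edge_sigma %||% 0.1,
                                r_fill = grid$spacing / 2)
    }
  }
  names(aps) <- as.character(plan$layers$layer_id)
  plan$apertures <- aps
  plan$collimated <- TRUE
  plan
}

#' Maximum boundary displacement between two apertures
#'
#' Symmetric Hausdorff-type distance between the boundary point sets of two
#' aperture contours; divided by the leaf speed it bounds the collimator
#' reconfiguration time between consecutive layers.
#'
#' @param a,b `aperture` objects.
#' @return Distance in cm.
#' @export
aperture_displacement <- function(a, b) {
  pa <- cbind(a$boundary, 0)
  pb <- cbind(b$boundary, 0)
  max(max(cpp_min_dist(pa, pb)), max(cpp_min_dist(pb, pa)))
}

#' @export
print.arc_plan <- function(x, ...) {
  cat("<arc_plan> ", length(x$angles), " directions, ",
      nrow(x$layers), " layers (", sum(x$layers$is_st), " ST), ",
      nrow(x$spots), " spots, ",
      if (x$collimated) "collimated" else "uncollimated",
      ", margin factor ", x$margin_factor, "\n", sep = "")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
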
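#' Specification of the virtual phantom
#'
#' The study geometry is a water ellipsoid ("External", half-axes 10 x 8.5 x
#' 10 cm) with four inclusions: an air cylinder (d = 2 cm, l = 5 cm, axis
#' along x, centre (+5.5, +3, 0)), a bone cylinder (d = 3.5 cm, l = 8 cm,
#' axis along x, centre (-5, -3, 0)), an OAR ellipsoid (half-axes 2 x 3 x
#' 4 cm, centre (0, +5, 0), anterior of the target) and one of three targets
#' centred at the origin:
#' \describe{
#'   \item{CTV_small}{cube with 3 cm sides (27 cm^3);}
#'   \item{CTV_4.5H}{4.5 cm cube minus two 1.5 x 1.5 x 4.5 cm cuboids
#'     (H-shape in the axial plane, 60.75 cm^3);}
#'   \item{CTV_6H}{6 cm cube minus two 2 x 2 x 6 cm cuboids (168 cm^3).}
#' }
#' The H cutouts run the full z-height and open towards +/- y, so the anterior
#' notch faces the OAR. All inclusion masks are clipped to the External
#' ellipsoid. SPR values: water 1.0, air 0.001, bone 1.6.
#'
#' The optional `asymmetric` variant welds a 4 cm-radius half-cylinder
#' "shoulder" (water) onto the right-inferior body surface; it stands in for
#' anatomy-change scenarios (e.g. a 2 cm shoulder shift).
#'
#' @param body_half_axes Half-axes (cm) of the External ellipsoid, (x, y, z).
#' @param spr Named list of SPR values for `water`, `air`, `bone`.
#' @param asymmetric Add the shoulder protrusion?
#' @return A `phantom_spec` list understood by [build_phantom()].
#' @export
phantom_spec <- function(body_half_axes = c(10, 8.5, 10),
                         spr = list(water = 1.0, air = 0.001, bone = 1.6),
                         asymmetric = FALSE) {
  structure(list(
    body_half_axes = body_half_axes,
    air_cyl = list(center = c(5.5, 3, 0), radius = 1.0, half_len = 2.5),
    bone_cyl = list(center = c(-5, -3, 0), radius = 1.75, half_len = 4.0),
    oar = list(center = c(0, 5, 0), half_axes = c(2, 3, 4)),
    shoulder = list(center_xz = c(8, -5), radius = 4, half_len_y = 4),
    spr = spr,
    asymmetric = isTRUE(asymmetric)
  ), class = "phantom_spec")
}

ctv_names <- c("CTV_small", "CTV_4.5H", "CTV_6H")

# target mask predicate at points (n x 3 matrix), centred at origin
ctv_inside <- function(target_choice, p) {
  x <- p[, 1]; y <- p[, 2]; z <- p[, 3]
  inside <- switch(target_choice,
    "CTV_small" = abs(x) < 1.5 & abs(y) < 1.5 & abs(z) < 1.5,
    "CTV_4.5H" = {
      cube <- abs(x) < 2.25 & abs(y) < 2.25 & abs(z) < 2.25
      cut <- abs(x) < 0.75 & abs(y) > 0.75 & abs(y) < 2.25
      cube & !cut
    },
    "CTV_6H" = {
      cube <- abs(x) < 3 & abs(y) < 3 & abs(z) < 3
      cut <- abs(x) < 1 & abs(y) > 1 & abs(y) < 3
      cube & !cut
    },
    stop("unknown target_choice: ", target_choice, call. = FALSE)
  )
  inside
}

#' Build the virtual phantom
#'
#' Rasterizes the phantom of [phantom_spec()] onto an isotropic voxel grid:
#' water SPR inside the External ellipsoid, air outside, with the air/bone
#' inclusions overriding the body, plus boolean ROI masks for External, the
#' chosen CTV, OAR, AirCyl and BoneCyl (and Shoulder for the asymmetric
#' variant). Exactly one CTV is active per phantom.
#'
#' @param spec A [phantom_spec()].
#' @param spacing Voxel size in cm, in (0, 1]; 0.25 for production geometry,
#'   0.5 for coarse desk-scale runs.
#' @param target_choice One of `"CTV_small"`, `"CTV_4.5H"`, `"CTV_6H"`.
#' @param margin Air margin (cm) added around the body when sizing the grid.
#' @return A list with elements `grid` (an [spr_grid()]), `rois` (named list
#'   of logical arrays) and `spec`.
#' @export
build_phantom <- function(spec = phantom_spec(), spacing = 0.25,
                          target_choice = "CTV_small", margin = 1) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (!(spacing > 0 && spacing <= 1)) {
    stop("`spacing` must be in (0, 1] cm", call. = FALSE)
  }
  if (!target_choice %in% ctv_names) {
    stop("unknown target_choice: ", target_choice,
         " (expected one of ", paste(ctv_names, collapse = ", "), ")",
         call. = FALSE)
  }
  a <- spec$body_half_axes
  lo <- c(-a[1] - margin, -a[2] - margin, -a[3] - margin)
  hi <- c(a[1] + margin, a[2] + margin, a[3] + margin)
  if (spec$asymmetric) {
    sh <- spec$shoulder
    hi[1] <- max(hi[1], sh$center_xz[1] + sh$radius + margin)
    hi[2] <- hi[2] + 2 + margin  # headroom for anatomy-change shifts
  }
  shape <- ceiling((hi - lo) / spacing)
  origin <- lo
  n <- prod(shape)

  idx <- seq_len(n)
  g0 <- spr_grid(array(0, dim = shape), spacing, origin)
  p <- voxel_centers(g0, idx)
  x <- p[, 1]; y <- p[, 2]; z <- p[, 3]

  body <- (x / a[1])^2 + (y / a[2])^2 + (z / a[3])^2 < 1
  if (spec$asymmetric) {
    sh <- spec$shoulder
    shoulder <- (x - sh$center_xz[1])^2 + (z - sh$center_xz[2])^2 <
      sh$radius^2 & x > sh$center_xz[1] & abs(y) < sh$half_len_y
    body <- body | shoulder
  } else {
    shoulder <- rep(FALSE, n)
  }

  cyl_mask <- function(cyl) {
    (y - cyl$center[2])^2 + (z - cyl$center[3])^2 < cyl$radius^2 &
      abs(x - cyl$center[1]) < cyl$half_len
  }
  air_cyl <- cyl_mask(spec$air_cyl) & body
  bone_cyl <- cyl_mask(spec$bone_cyl) & body
  o <- spec$oar
  oar <- ((x - o$center[1]) / o$half_axes[1])^2 +
    ((y - o$center[2]) / o$half_axes[2])^2 +
    ((z - o$center[3]) / o$half_axes[3])^2 < 1
  oar <- oar & body
  ctv <- ctv_inside(target_choice, p) & body

  spr <- rep(spec$spr$air, n)
  spr[body] <- spec$spr$water
  spr[air_cyl] <- spec$spr$air
  spr[bone_cyl] <- spec$spr$bone

  dim3 <- shape
  as_arr <- function(v) array(v, dim = dim3)
  rois <- list(
    External = as_arr(body),
    CTV = as_arr(ctv),
    OAR = as_arr(oar),
    AirCyl = as_arr(air_cyl),
    BoneCyl = as_arr(bone_cyl)
  )
  names(rois)[2] <- target_choice
  if (spec$asymmetric) rois$Shoulder <- as_arr(shoulder)

  list(grid = spr_grid(as_arr(spr), spacing, origin), rois = rois,
       spec = spec, target = target_choice)
}

#' Scale the SPR inside a region
#'
#' Multiplies the SPR by `factor` inside `region` (default: every voxel),
#' leaving the rest untouched. Used for systematic range/density perturbations
#' such as a 5% SPR shift of the whole patient volume; by linearity of the
#' line integral, a whole-body scale multiplies every WET by the same factor.
#'
#' @param grid A [spr_grid()].
#' @param factor Positive scale factor.
#' @param region Optional logical mask on the grid; `NULL` scales everywhere.
#' @return A new [spr_grid()]; the input is unchanged.
#' @export
scale_spr <- function(grid, factor, region = NULL) {
  stopifnot(inherits(grid, "spr_grid"))
  if (!is.numeric(factor) || length(factor) != 1 || factor <= 0) {
    stop("`factor` must be a single positive number", call. = FALSE)
  }
  spr <- grid$spr
  if (is.null(region)) {
    spr <- spr * factor
  } else {
    check_mask(region, grid)
    spr[region] <- spr[region] * factor
  }
  spr_grid(spr, grid$spacing, grid$origin)
}

#' Rigidly shift the grid content
#'
#' Translates the SPR content by `vector` (cm) with nearest-neighbour
#' resampling (the shift is rounded to whole voxel pitches, which preserves
#' discrete material classes exactly). Voxels entering from outside the grid
#' are filled with air SPR.
#'
#' @param grid A [spr_grid()].
#' @param vector Length-3 shift in cm (patient frame).
#' @param fill SPR value for vacated voxels (default air, 0.001).
#' @return A new [spr_grid()].
#' @export
shift_geometry <- function(grid, vector, fill = 0.001) {
  stopifnot(inherits(grid, "spr_grid"), length(vector) == 3)
  d <- grid$shape
  sv <- round(vector / grid$spacing)
  if (any(abs(sv) >= d)) stop("shift exceeds grid extent", call. = FALSE)
  out <- array(fill, dim = d)
  src <- dst <- vector("list", 3)
  for (a in 1:3) {
    s <- sv[a]
    if (s >= 0) {
      src[[a]] <- seq_len(d[a] - s)
      dst[[a]] <- seq_len(d[a] - s) + s
    } else {
      src[[a]] <- seq_len(d[a] + s) - s
      dst[[a]] <- seq_len(d[a] + s)
    }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- grid$spr[src[[1]], src[[2]], src[[3]]]
  spr_grid(out, grid$spacing, grid$origin)
}

#' Displace a sub-volume of the grid
#'
#' Moves the SPR content inside `region` by `vector` (rounded to whole voxel
#' pitches). Vacated voxels are set to `fill` (air); overwritten voxels take
#' the moved values. Models localized anatomy changes such as a 2 cm shoulder
#' shift.
#'
#' @param grid A [spr_grid()].
#' @param region Logical mask of the voxels to move.
#' @param vector Length-3 displacement in cm.
#' @param fill SPR value left behind (default air, 0.001).
#' @return A new [spr_grid()].
#' @export
displace_subvolume <- function(grid, region, vector, fill = 0.001) {
  stopifnot(inherits(grid, "spr_grid"))
  check_mask(region, grid)
  if (!any(region)) return(grid)
  d <- grid$shape
  sv <- as.integer(round(vector / grid$spacing))
  idx <- which(region)
  idx0 <- idx - 1L
  i <- idx0 %% d[1] + sv[1]
  j <- (idx0 %/% d[1]) %% d[2] + sv[2]
  k <- idx0 %/% (d[1] * d[2]) + sv[3]
  if (any(i < 0 | i >= d[1] | j < 0 | j >= d[2] | k < 0 | k >= d[3])) {
    stop("displaced region falls outside the grid", call. = FALSE)
  }
  dest <- i + d[1] * (j + d[2] * k) + 1L
  spr <- grid$spr
  vals <- spr[idx]
  spr[idx] <- fill
  spr[dest] <- vals
  spr_grid(spr, grid$spacing, grid$origin)
}
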
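#' Voxelized stopping-power-ratio grid
#'
#' A `spr_grid` holds a dimensionless stopping-power-ratio (SPR) value per
#' voxel on an isotropic grid in the patient frame (x = left, y = anterior,
#' z = superior, units cm). Voxel `(i,j,k)` (0-based) spans the half-open box
#' `[origin + i*spacing, origin + (i+1)*spacing)` per axis. Water has SPR 1,
#' air ~0.001, cortical-bone-like material 1.6; every ray-trace and dose
#' computation traverses this grid.
#'
#' @param spr Numeric 3-D array of SPR values (finite, >= 0).
#' @param spacing Isotropic voxel size in cm (> 0).
#' @param origin Numeric length-3: position (cm) of the corner of voxel
#'   (0,0,0).
#' @return An object of class `spr_grid`.
#' @export
spr_grid <- function(spr, spacing, origin) {
  stopifnot(is.array(spr), length(dim(spr)) == 3)
  if (!is.numeric(spacing) || length(spacing) != 1 || spacing <= 0) {
    stop("`spacing` must be a single positive number (cm)", call. = FALSE)
  }
  if (length(origin) != 3) stop("`origin` must have length 3", call. = FALSE)
  if (any(!is.finite(spr)) || any(spr < 0)) {
    stop("SPR values must be finite and non-negative", call. = FALSE)
  }
  structure(
    list(spr = spr, spacing = as.numeric(spacing),
         origin = as.numeric(origin), shape = dim(spr)),
    class = "spr_grid"
  )
}

#' @export
print.spr_grid <- function(x, ...) {
  cat("<spr_grid> ", paste(x$shape, collapse = " x "),
      " voxels, spacing ", x$spacing, " cm, origin (",
      paste(format(x$origin), collapse = ", "), ") cm\n", sep = "")
  cat("  SPR range [", format(min(x$spr)), ", ", format(max(x$spr)), "]\n",
      sep = "")
  invisible(x)
}

#' Voxel-centre coordinates
#'
#' @param grid A [spr_grid()].
#' @param idx Optional integer vector of 1-based linear voxel indices; default
#'   all voxels.
#' @return An n x 3 matrix of voxel-centre coordinates (cm).
#' @export
voxel_centers <- function(grid, idx = NULL) {
  d <- grid$shape
  if (is.null(idx)) idx <- seq_len(prod(d))
  idx0 <- idx - 1L
  i <- idx0 %% d[1]
  j <- (idx0 %/% d[1]) %% d[2]
  k <- idx0 %/% (d[1] * d[2])
  cbind(
    grid$origin[1] + (i + 0.5) * grid$spacing,
    grid$origin[2] + (j + 0.5) * grid$spacing,
    grid$origin[3] + (k + 0.5) * grid$spacing
  )
}

#' Volume represented by a logical mask on a grid
#'
#' @param mask Logical array on the grid's voxel lattice.
#' @param grid The [spr_grid()] the mask lives on.
#' @return Volume in cm^3 (`count * spacing^3`).
#' @export
mask_volume <- function(mask, grid) sum(mask) * grid$spacing^3

# internal: check that a mask conforms to a grid
check_mask <- function(mask, grid) {
  stopifnot(is.logical(mask), identical(dim(mask), grid$shape))
  invisible(TRUE)
}
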
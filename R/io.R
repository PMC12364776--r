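#' Write / read a voxel grid as NRRD
#'
#' Minimal NRRD (ascii encoding) I/O for SPR grids, dose grids and masks: a
#' single scalar volume with spacing and origin recorded in the header.
#' Round-trips losslessly at full double precision.
#'
#' @param grid A [spr_grid()] (or a numeric/logical array plus `spacing`,
#'   `origin`).
#' @param path Output file.
#' @export
write_grid <- function(grid, path) {
  stopifnot(inherits(grid, "spr_grid"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "NRRD0004",
    "# starc voxel grid",
    "type: double",
    "dimension: 3",
    sprintf("sizes: %d %d %d", grid$shape[1], grid$shape[2], grid$shape[3]),
    sprintf("spacings: %.17g %.17g %.17g", grid$spacing, grid$spacing,
            grid$spacing),
    sprintf("axis mins: %.17g %.17g %.17g", grid$origin[1], grid$origin[2],
            grid$origin[3]),
    "encoding: ascii",
    ""), con)
  writeLines(sprintf("%.17g", as.vector(grid$spr)), con)
}

#' @rdname write_grid
#' @return `read_grid`: the [spr_grid()].
#' @export
read_grid <- function(path) {
  lines <- readLines(path)
  if (!startsWith(lines[1], "NRRD")) {
    stop("not an NRRD file: ", path, call. = FALSE)
  }
  blank <- which(lines == "")[1]
  if (is.na(blank)) stop("malformed NRRD: missing header terminator",
                         call. = FALSE)
  header <- lines[seq_len(blank - 1)]
  field <- function(name) {
    ln <- grep(paste0("^", name, ": "), header, value = TRUE)
    if (length(ln) == 0) stop("malformed NRRD: missing field '", name, "'",
                              call. = FALSE)
    strsplit(sub(paste0("^", name, ": "), "", ln[1]), " +")[[1]]
  }
  enc <- field("encoding")
  if (enc != "ascii") stop("unsupported NRRD encoding: ", enc, call. = FALSE)
  sizes <- as.integer(field("sizes"))
  spacing <- as.numeric(field("spacings"))[1]
  origin <- as.numeric(field("axis mins"))
  vals <- as.numeric(lines[(blank + 1):length(lines)])
  vals <- vals[!is.na(vals)]
  if (length(vals) != prod(sizes)) {
    stop("malformed NRRD: expected ", prod(sizes), " values, got ",
         length(vals), call. = FALSE)
  }
  spr_grid(array(vals, dim = sizes), spacing, origin)
}

#' Write / read a plan as JSON
#'
#' Lossless JSON serialization of an `arc_plan`: angles, layers, spots (with
#' MU and flags) and metadata. Apertures are rebuilt from geometry on read
#' when the plan is collimated, so only their defining margin travels in the
#' file.
#'
#' @param plan An `arc_plan`.
#' @param path Output file.
#' @export
write_plan <- function(plan, path) {
  stopifnot(inherits(plan, "arc_plan"))
  obj <- list(
    format = "starc_plan_v1",
    angles = plan$angles,
    collimated = plan$collimated,
    margin_factor = plan$margin_factor,
    spot_spacing = plan$spot_spacing,
    prescription = plan$prescription,
    fractions = plan$fractions,
    layers = plan$layers,
    spots = plan$spots
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       dataframe = "columns")
}

#' @rdname write_plan
#' @param phantom,bm Needed to rebuild apertures for collimated plans;
#'   optional otherwise.
#' @return `read_plan`: the `arc_plan`.
#' @export
read_plan <- function(path, phantom = NULL, bm = NULL) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$format) || obj$format != "starc_plan_v1") {
    stop("not a starc plan file (missing/unknown 'format'): ", path,
         call. = FALSE)
  }
  for (f in c("angles", "layers", "spots", "prescription")) {
    if (is.null(obj[[f]])) {
      stop("malformed plan file: missing field '", f, "'", call. = FALSE)
    }
  }
  plan <- structure(list(
    spots = tibble::as_tibble(obj$spots),
    layers = tibble::as_tibble(obj$layers),
    angles = obj$angles,
    collimated = isTRUE(obj$collimated),
    margin_factor = obj$margin_factor,
    spot_spacing = obj$spot_spacing,
    prescription = obj$prescription,
    fractions = obj$fractions,
    apertures = NULL
  ), class = "arc_plan")
  if (plan$collimated) {
    if (is.null(phantom) || is.null(bm)) {
      warning("collimated plan read without phantom/beam model; ",
              "apertures not rebuilt")
    } else {
      plan <- add_apertures(plan, phantom, bm)
    }
  }
  plan
}

#' Write a plan-metrics report
#'
#' JSON metrics plus a human-readable fixed-width table mirroring the
#' study's reporting columns.
#'
#' @param metrics A `plan_metrics` tibble (one row per plan) with a
#'   `plan_name` column, or a named list of such rows.
#' @param path Output path without extension; writes `<path>.json` and
#'   `<path>.txt`.
#' @export
write_report <- function(metrics, path) {
  if (nrow(metrics) == 0) stop("no plans to report", call. = FALSE)
  jsonlite::write_json(metrics, paste0(path, ".json"), digits = NA,
                       dataframe = "rows", auto_unbox = TRUE)
  txt <- utils::capture.output(print(as.data.frame(metrics), digits = 4,
                                     row.names = FALSE))
  writeLines(txt, paste0(path, ".txt"))
  invisible(path)
}
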
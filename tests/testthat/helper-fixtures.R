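# Shared fixtures, memoised across test files (one R session per test run).
# The desk-scale study geometry: 5 mm grid, 20-direction arcs, CTV_small.

.cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (is.null(.cache[[name]])) .cache[[name]] <- force(expr)
  .cache[[name]]
}

bm_fix <- function() cached("bm", beam_model())

phantom_fix <- function(target = "CTV_small", asymmetric = FALSE) {
  cached(paste0("ph_", target, "_", asymmetric),
         build_phantom(phantom_spec(asymmetric = asymmetric),
                       spacing = 0.5, target_choice = target))
}

# Arc+ST plan skeleton used by verification tests (Bragg layer count is
# irrelevant for shoot-through ray tracing, so keep it small)
verification_plan <- function(asymmetric = FALSE) {
  cached(paste0("vplan_", asymmetric), {
    ph <- phantom_fix(asymmetric = asymmetric)
    bm <- bm_fix()
    plan <- build_plan(ph, bm, n_layers_per_direction = 4)
    add_st_layer(plan, ph, bm)
  })
}

# Optimized study plans (Arc+ST, Arc, Arc+Coll) on the 5 mm CTV_small
# phantom under the identical default objective configuration. Heavy; built
# once and reused by the optimizer, evaluation and acceptance tests.
smoke_plan <- function(kind = c("arc_st", "arc", "arc_coll")) {
  kind <- match.arg(kind)
  cached(paste0("smoke_", kind), {
    ph <- phantom_fix()
    bm <- bm_fix()
    coll <- kind == "arc_coll"
    plan <- build_plan(ph, bm, n_layers_per_direction = 24,
                       margin_factor = if (coll) 1.25 else 1.0,
                       collimated = coll)
    if (kind == "arc_st") plan <- add_st_layer(plan, ph, bm)
    prob <- optimization_problem(ph, plan, bm)
    res <- optimize_weights(prob, final_layers = 240)
    dose <- as.numeric(prob$infl_nom %*% res$weights)
    list(phantom = ph, bm = bm, plan = res$plan, problem = prob, result = res,
         dose = dose, ctv = prob$roi_nom$CTV)
  })
}

# a minimal hand-built arc_plan for unit tests that need full control
fake_plan <- function(spots, angles, collimated = FALSE, prescription = 60) {
  spots <- tibble::as_tibble(spots)
  if (!"spot_id" %in% names(spots)) spots$spot_id <- seq_len(nrow(spots))
  layers <- unique(as.data.frame(
    spots[, c("layer_id", "dir_index", "angle", "energy", "is_st")]))
  layers <- tibble::as_tibble(layers)
  structure(list(spots = spots, layers = layers, angles = angles,
                 collimated = collimated, margin_factor = 1,
                 spot_spacing = 0.6, prescription = prescription,
                 fractions = 30, apertures = NULL),
            class = "arc_plan")
}

# uniform box of given SPR centred at the origin
water_box <- function(n = c(24, 24, 24), spacing = 0.5, spr = 1) {
  spr_grid(array(spr, dim = n), spacing, -n * spacing / 2)
}

# brute-force fine-step WET oracle (midpoint sampling of voxel SPR)
wet_oracle <- function(grid, p0, dir, step = 0.01, tmax = 80) {
  dir <- dir / sqrt(sum(dir^2))
  t <- seq(step / 2, tmax, by = step)
  px <- outer(t, dir[1]) + p0[1]
  py <- outer(t, dir[2]) + p0[2]
  pz <- outer(t, dir[3]) + p0[3]
  i <- floor((px - grid$origin[1]) / grid$spacing)
  j <- floor((py - grid$origin[2]) / grid$spacing)
  k <- floor((pz - grid$origin[3]) / grid$spacing)
  d <- grid$shape
  ok <- i >= 0 & i < d[1] & j >= 0 & j < d[2] & k >= 0 & k < d[3]
  idx <- i[ok] + d[1] * (j[ok] + d[2] * k[ok]) + 1
  sum(grid$spr[idx]) * step
}
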
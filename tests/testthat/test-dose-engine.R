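test_that("voxel-walking WET matches hand-computed values", {
  # 10 cm of water along the middle of a water box
  g <- water_box(c(24, 24, 24), spacing = 0.5)
  w <- wet_along_ray(g, c(0, 5.9, 0), c(0, -1, 0), length = 10)
  expect_equal(w, 10, tolerance = 1e-9)
  # 2 cm bone (SPR 1.6) + 8 cm water = 11.2 cm WET
  m <- g$spr
  m[, 21:24, ] <- 1.6  # y in [4, 6): 2 cm slab
  gb <- spr_grid(m, g$spacing, g$origin)
  w2 <- wet_along_ray(gb, c(0.1, 6, 0.1), c(0, -1, 0), length = 10)
  expect_equal(w2, 2 * 1.6 + 8, tolerance = 1e-9)
  expect_error(wet_along_ray(g, c(0, 0, 0), c(0, 0, 0)), "zero direction")
})

test_that("voxel walking agrees with a fine-step integration oracle", {
  ph <- phantom_fix("CTV_small")
  set.seed(42)
  n <- 25
  targets <- cbind(runif(n, -6, 6), runif(n, -5, 5), runif(n, -6, 6))
  theta <- runif(n, 0, 2 * pi); phi <- acos(runif(n, -0.7, 0.7))
  dirs <- cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
  p0 <- targets - 30 * dirs
  w_fast <- wet_along_ray(ph$grid, p0, dirs)
  for (i in seq_len(n)) {
    w_ref <- wet_oracle(ph$grid, p0[i, ], dirs[i, ])
    expect_lt(abs(w_fast[i] - w_ref) / w_ref, 0.005)
  }
})

test_that("dose is linear in spot weights and per-unit-MU columns exist", {
  sm <- smoke_plan("arc_st")
  infl <- sm$problem$infl_nom
  w <- sm$result$weights
  d1 <- as.numeric(infl %*% w)
  d2 <- as.numeric(infl %*% (2 * w))
  expect_equal(d2, 2 * d1, tolerance = 1e-12)
  w_a <- w; w_a[seq(1, length(w), 2)] <- 0
  w_b <- w - w_a
  expect_equal(as.numeric(infl %*% w_a) + as.numeric(infl %*% w_b), d1,
               tolerance = 1e-12)
  # zero-MU spots still have defined per-unit-MU columns
  zero_spots <- which(w == 0)
  expect_gt(length(zero_spots), 0)
  expect_true(all(infl@x >= 0))
})

test_that("a shoot-through spot has no Bragg peak inside the body", {
  ph <- phantom_fix("CTV_small")
  bm <- bm_fix()
  plan <- verification_plan()
  st_ids <- plan$spots$spot_id[plan$spots$is_st &
                                abs(plan$spots$u) < 0.3 &
                                abs(plan$spots$v) < 0.3]
  d <- spot_dose(ph$grid, plan, st_ids[1], bm)
  # dose along the beam axis within the body: quasi-flat plateau
  ctr <- voxel_centers(ph$grid)
  on_axis <- abs(ctr[, 1]) < 0.3 & abs(ctr[, 3]) < 0.3 &
    ph$rois$External & abs(ctr[, 2]) < 7.5
  prof <- d[on_axis]
  expect_gt(min(prof), 0)
  expect_lt(max(prof) / min(prof), 1.5)
})

test_that("density scaling pulls Bragg peaks shallower", {
  ph <- phantom_fix("CTV_small")
  bm <- bm_fix()
  plan <- verification_plan()
  bragg <- plan$spots[!plan$spots$is_st & plan$spots$dir_index == 1, ]
  mid <- bragg[which.min(abs(bragg$u) + abs(bragg$v)), ]
  dn <- spot_dose(ph$grid, plan, mid$spot_id, bm)
  dd <- spot_dose(ph$grid, plan, mid$spot_id, bm,
                  make_scenario(spr_scale = 1.035, label = "dense"))
  ctr <- voxel_centers(ph$grid)
  axis <- abs(ctr[, 1] - mid$u) < 0.3 & abs(ctr[, 3] - mid$v) < 0.3
  # peak position in y (beam from +y): denser medium stops protons earlier
  y_peak_nom <- ctr[axis, 2][which.max(dn[axis])]
  y_peak_dense <- ctr[axis, 2][which.max(dd[axis])]
  expect_gte(y_peak_dense, y_peak_nom)
})

test_that("collimation cannot increase integral body dose", {
  ph <- phantom_fix("CTV_small")
  bm <- bm_fix()
  plan <- build_plan(ph, bm, angles = 0, n_layers_per_direction = 3,
                     margin_factor = 1.25, collimated = FALSE)
  plan_c <- starc:::add_apertures(plan, ph, bm)
  ext <- which(ph$rois$External)
  i_open <- influence_matrix(ph$grid, plan, bm, rows = ext)
  i_coll <- influence_matrix(ph$grid, plan_c, bm, rows = ext)
  w <- rep(1, nrow(plan$spots))
  expect_lte(sum(i_coll %*% w), sum(i_open %*% w))
  # and every voxel dose is <= the open-field dose
  expect_true(all(as.numeric(i_coll %*% w) <=
                    as.numeric(i_open %*% w) + 1e-9))
})
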
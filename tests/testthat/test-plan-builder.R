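test_that("arc directions are uniform from zero", {
  expect_equal(make_arc_directions(20), seq(0, 342, by = 18))
  expect_equal(make_arc_directions(1), 0)
  expect_equal(make_arc_directions(4), c(0, 90, 180, 270))
})

test_that("energy-layer selection samples the target WET interval", {
  ph <- phantom_fix("CTV_small")
  bm <- bm_fix()
  sel <- select_energy_layers(ph$grid, ph$rois$CTV_small, 0, 24, bm)
  expect_true(all(diff(sel$range) > 0))
  # CTV_small at 0 deg: skin-to-target water depths ~ [7, 10] cm
  expect_gt(min(sel$range), 5.5)
  expect_lt(max(sel$range), 11.5)
  # two layers pick the nearest machine levels to the interval endpoints
  s2 <- select_energy_layers(ph$grid, ph$rois$CTV_small, 0, 2, bm)
  expect_equal(nrow(s2), 2)
  expect_equal(s2$range, range(sel$range), tolerance = 0.3)
  s1 <- select_energy_layers(ph$grid, ph$rois$CTV_small, 0, 1, bm)
  expect_equal(nrow(s1), 1)
  expect_gt(s1$range, min(sel$range))
  expect_lt(s1$range, max(sel$range))
  empty <- array(FALSE, dim = ph$grid$shape)
  expect_error(select_energy_layers(ph$grid, empty, 0, 4, bm), "empty")
})

test_that("spot placement respects margins and lattice density", {
  ph <- phantom_fix("CTV_small")
  bm <- bm_fix()
  # margin example: 1.25 x sigma_air(230 MeV) = 0.50 cm
  expect_equal(1.25 * sigma_air(230, bm), 0.50)
  pos <- place_spots(ph$grid, ph$rois$CTV_small, 0, 230,
                     margin_factor = 1.25, spot_spacing = 0.6, bm = bm)
  # projection of a 3 cm cube is [-1.5, 1.5]^2; dilated by 0.5 cm
  expect_true(all(abs(pos) <= 1.5 + 0.5 + 1e-9))
  pos0 <- place_spots(ph$grid, ph$rois$CTV_small, 0, 230,
                      margin_factor = 0, spot_spacing = 0.6, bm = bm)
  expect_true(all(abs(pos0) <= 1.5 + 1e-9))
  expect_gt(nrow(pos), nrow(pos0))
  # halving the spacing roughly quadruples the count
  pos_half <- place_spots(ph$grid, ph$rois$CTV_small, 0, 230,
                          margin_factor = 1.25, spot_spacing = 0.3, bm = bm)
  expect_gt(nrow(pos_half) / nrow(pos), 2.5)
  expect_lt(nrow(pos_half) / nrow(pos), 6)
})

test_that("shoot-through layers cover the full projection at 230 MeV", {
  plan <- verification_plan()
  st <- plan$layers[plan$layers$is_st, ]
  expect_equal(nrow(st), 20)              # one per direction
  expect_true(all(st$energy == 230))
  expect_error(add_st_layer(plan, phantom_fix(), bm_fix()), "already has")
  # the ST layer covers every Bragg layer's WET-slab projection: at the ST
  # energy and margin, each slab's spot set is a subset of the ST layer's
  ph <- phantom_fix()
  bm <- bm_fix()
  for (di in c(1, 6)) {
    ang <- plan$angles[di]
    st_pos <- plan$spots[plan$spots$dir_index == di & plan$spots$is_st, ]
    st_key <- paste(st_pos$u, st_pos$v)
    lay <- plan$layers[plan$layers$dir_index == di & !plan$layers$is_st, ]
    for (r in seq_len(min(nrow(lay), 3))) {
      slab <- place_spots(ph$grid, ph$rois$CTV_small, ang, 230,
                          plan$margin_factor, plan$spot_spacing,
                          wed_window = c(lay$wed_lo[r], lay$wed_hi[r]),
                          bm = bm)
      expect_true(all(paste(slab[, 1], slab[, 2]) %in% st_key))
      expect_gte(nrow(st_pos), nrow(slab))
    }
  }
})

test_that("every spot ray intersects the dilated target projection", {
  plan <- verification_plan()
  ph <- phantom_fix()
  bm <- bm_fix()
  tgt_idx <- which(ph$rois$CTV_small)
  pts <- voxel_centers(ph$grid, tgt_idx)
  for (di in c(1, 5, 14)) {
    fr <- starc:::beam_frame(plan$angles[di])
    uv <- cbind(pts %*% fr$u, pts %*% fr$v)
    sp <- plan$spots[plan$spots$dir_index == di, ]
    margin <- plan$margin_factor * sigma_air(sp$energy, bm)
    dmin <- vapply(seq_len(nrow(sp)), function(i) {
      min(sqrt((uv[, 1] - sp$u[i])^2 + (uv[, 2] - sp$v[i])^2))
    }, numeric(1))
    # within margin plus half a lattice diagonal of some target voxel
    expect_true(all(dmin <= margin + 0.61))
  }
})

test_that("apertures follow non-convex layer projections with sound edges", {
  # an H-target's mid-depth WET slab projects to two disconnected bars
  bars <- expand.grid(u = c(seq(-3, -1.5, 0.5), seq(1.5, 3, 0.5)),
                      v = seq(-2, 2, 0.5))
  ap <- make_aperture(bars, margin = 0.3, r_fill = 0.25)
  # contour = margin + footprint = 0.55 cm beyond the bar points
  # deep inside a bar: fully transparent; between the bars: opaque
  expect_equal(aperture_transmission(-2.25, 0, ap), 1, tolerance = 1e-6)
  expect_lt(aperture_transmission(0, 0, ap), 0.01)
  # 1 cm outside the field: < 1e-6
  expect_lt(aperture_transmission(4.6, 0, ap), 1e-6)
  # on the contour: half transmission
  expect_equal(aperture_transmission(3.55, 0, ap), 0.5, tolerance = 0.05)
})

test_that("plan serialization round-trips losslessly", {
  plan <- verification_plan()
  f <- tempfile(fileext = ".json")
  write_plan(plan, f)
  back <- read_plan(f)
  expect_equal(back$spots$u, plan$spots$u)
  expect_equal(back$spots$mu, plan$spots$mu)
  expect_equal(back$spots$is_st, plan$spots$is_st)
  expect_equal(back$angles, plan$angles)
  expect_equal(back$prescription, plan$prescription)
  unlink(f)
})
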
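test_that("residual range subtracts the traced WET from the machine range", {
  bm <- bm_fix()
  r_max <- range_in_water(230, bm)
  # 20 cm water chord leaves ~13.3 cm of range
  g <- water_box(c(20, 44, 20), spacing = 0.5)  # 22 cm of water along y
  r <- residual_range(g, c(0.1, 30, 0.1), c(0, -1, 0), r_max)
  expect_equal(r, r_max - 22, tolerance = 1e-9)
  # a ray missing the grid entirely keeps the full range
  expect_equal(residual_range(g, c(50, 30, 0), c(0, -1, 0), r_max), r_max)
  # bone shortens the residual range relative to water
  m <- g$spr
  m[, 1:8, ] <- 1.6
  gb <- spr_grid(m, g$spacing, g$origin)
  expect_lt(residual_range(gb, c(0.1, 30, 0.1), c(0, -1, 0), r_max), r)
})

test_that("the relative WET difference follows its defining arithmetic", {
  expect_equal(delta_wet(12, 12, 32), 0)
  expect_equal(delta_wet(12, 11, 32), 0.05)
  expect_equal(delta_wet(13.3, 12.3, 33.3), 1 / 20)
  # positive means shorter measured range (more material than planned)
  expect_gt(delta_wet(10, 9, 30), 0)
  expect_lt(delta_wet(10, 11, 30), 0)
  expect_error(delta_wet(33, 10, 33), "undefined")
})

test_that("swapping plan and measurement grids antisymmetrizes delta", {
  set.seed(3)
  r_max <- 33.3
  r_plan <- runif(20, 5, 25)
  r_meas <- r_plan + runif(20, -2, 2)
  fwd <- delta_wet(r_plan, r_meas, r_max)
  swp <- delta_wet(r_meas, r_plan, r_max)
  expect_equal(swp, -fwd * (r_max - r_plan) / (r_max - r_meas),
               tolerance = 1e-12)
})

test_that("a uniform SPR scale is recovered exactly at every angle", {
  ph <- phantom_fix()
  bm <- bm_fix()
  plan <- verification_plan()
  rec <- run_verification(plan, ph$grid, scale_spr(ph$grid, 1.05), bm)
  ok <- !rec$flagged
  expect_gt(sum(ok), 500)
  expect_equal(rec$delta_wet[ok], rep(0.05, sum(ok)), tolerance = 1e-9)
  # identity scenario: all zero
  rec0 <- run_verification(plan, ph$grid, ph$grid, bm)
  expect_true(all(rec0$delta_wet == 0))
  plan_no <- plan
  plan_no$spots <- plan$spots[!plan$spots$is_st, ]
  expect_error(run_verification(plan_no, ph$grid, ph$grid, bm),
               "shoot-through")
})

test_that("per-angle summaries follow the box-plot whisker convention", {
  rec <- tibble::tibble(
    spot_id = 1:5, dir_index = 1, angle = 0, u = 1:5, v = 0,
    r_plan = 10, r_measured = 10, r_max = 33,
    delta_wet = c(1, 2, 3, 4, 100), flagged = FALSE)
  s <- summarize_by_angle(rec)
  expect_equal(s$median, 3)
  expect_equal(s$q1, 2)
  expect_equal(s$q3, 4)
  # 100 lies beyond Q3 + 1.5 IQR = 7: excluded from the whisker
  expect_equal(s$whisker_high, 4)
  expect_equal(s$whisker_low, 1)
  single <- rec[3, ]
  s1 <- summarize_by_angle(single)
  expect_equal(s1$median, s1$q1)
  expect_equal(s1$q1, s1$q3)
  # flagged records never enter the statistics
  rec$flagged[5] <- TRUE
  expect_equal(summarize_by_angle(rec)$median, 2.5)
})

test_that("the spot map caps displayed differences at 15 percent", {
  rec <- tibble::tibble(
    spot_id = 1:3, dir_index = 1, angle = 0, u = 1:3, v = 0,
    r_plan = 10, r_measured = 10, r_max = 33,
    delta_wet = c(0.30, -0.2, 0.02), flagged = FALSE)
  sm <- spot_map(rec)
  expect_equal(sm$delta_capped, c(0.15, -0.15, 0.02))
  expect_equal(sm$delta_wet, rec$delta_wet)  # raw values preserved
})

test_that("rays missing the body are flagged and excluded", {
  bm <- bm_fix()
  # a plan whose ST spots sit far outside the small water box
  sp <- tibble::tibble(layer_id = 1, dir_index = 1, angle = 0,
                       energy = 230, u = c(0, 30), v = 0,
                       mu = 0.2, is_st = TRUE)
  plan <- fake_plan(sp, angles = 0)
  g <- water_box(c(24, 24, 24), spacing = 0.5)
  rec <- run_verification(plan, g, scale_spr(g, 1.05), bm)
  expect_equal(rec$flagged, c(FALSE, TRUE))
  expect_equal(rec$delta_wet[2], 0)
  expect_equal(rec$delta_wet[1], 0.05, tolerance = 1e-9)
})
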
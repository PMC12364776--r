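test_that("rasterized ROI volumes match analytic solid geometry", {
  ph <- phantom_fix("CTV_small")
  g <- ph$grid
  # one-voxel-shell tolerance: surface area times voxel size
  shell <- function(area_cm2) area_cm2 * g$spacing

  # External ellipsoid (4/3) pi a b c; surface ~ 1015 cm^2
  v_ext <- mask_volume(ph$rois$External, g)
  expect_lt(abs(v_ext - 4 / 3 * pi * 10 * 8.5 * 10), shell(1015))

  expect_lt(abs(mask_volume(ph$rois$CTV_small, g) - 27), shell(6 * 9))

  ph6 <- phantom_fix("CTV_6H")
  v6 <- mask_volume(ph6$rois$CTV_6H, ph6$grid)
  expect_lt(abs(v6 - (6^3 - 2 * (2 * 2 * 6))), shell(300))

  ph45 <- phantom_fix("CTV_4.5H")
  v45 <- mask_volume(ph45$rois$`CTV_4.5H`, ph45$grid)
  expect_lt(abs(v45 - (4.5^3 - 2 * (1.5 * 1.5 * 4.5))), shell(200))
})

test_that("rasterization error shrinks as the grid is refined", {
  coarse <- phantom_fix("CTV_6H")
  fine <- build_phantom(spacing = 0.25, target_choice = "CTV_6H")
  v_true <- 168
  err <- function(ph) abs(mask_volume(ph$rois$CTV_6H, ph$grid) - v_true)
  expect_lt(err(fine), err(coarse) + 1e-9)
  e_true <- 4 / 3 * pi * 10 * 8.5 * 10
  err_e <- function(ph) abs(mask_volume(ph$rois$External, ph$grid) - e_true)
  expect_lt(err_e(fine), err_e(coarse))
})

test_that("all ROIs are contained in External and one CTV is active", {
  ph <- phantom_fix("CTV_small")
  ext <- ph$rois$External
  for (nm in setdiff(names(ph$rois), "External")) {
    expect_true(all(ext[ph$rois[[nm]]]), label = paste(nm, "inside External"))
  }
  expect_length(intersect(names(ph$rois),
                          c("CTV_small", "CTV_4.5H", "CTV_6H")), 1)
  expect_error(build_phantom(target_choice = "CTV_huge"), "target_choice")
})

test_that("scale_spr is local, invertible and linear in WET", {
  ph <- phantom_fix("CTV_small")
  g <- ph$grid
  expect_equal(scale_spr(g, 1)$spr, g$spr)
  g2 <- scale_spr(scale_spr(g, 1.05), 1 / 1.05)
  expect_equal(g2$spr, g$spr, tolerance = 1e-12)

  # whole-body scale multiplies every WET by exactly the factor
  set.seed(1)
  p0 <- cbind(runif(10, -3, 3), 30, runif(10, -3, 3))
  dir <- matrix(rep(c(0, -1, 0), each = 10), ncol = 3)
  w1 <- wet_along_ray(g, p0, dir)
  w2 <- wet_along_ray(scale_spr(g, 1.05), p0, dir)
  expect_equal(w2, w1 * 1.05, tolerance = 1e-12)

  # scaling only the bone cylinder changes only bone-crossing rays
  gb <- scale_spr(g, 0.95, ph$rois$BoneCyl)
  # bone cylinder centre (-5,-3,0): a ray through it vs one far from it
  hit <- wet_along_ray(g, c(-5, 30, 0), c(0, -1, 0))
  hit2 <- wet_along_ray(gb, c(-5, 30, 0), c(0, -1, 0))
  expect_lt(hit2, hit)
  miss <- wet_along_ray(g, c(5.0, 30, 5), c(0, -1, 0))
  miss2 <- wet_along_ray(gb, c(5.0, 30, 5), c(0, -1, 0))
  expect_equal(miss, miss2)
})

test_that("shift_geometry translates content and conserves SPR mass", {
  g <- water_box(c(12, 12, 12), spacing = 0.5, spr = 0.001)
  m <- g$spr
  m[6, 6, 6] <- 1.6  # single-voxel marker
  g <- spr_grid(m, g$spacing, g$origin)
  expect_equal(shift_geometry(g, c(0, 0, 0))$spr, g$spr)
  gs <- shift_geometry(g, c(0.5, 0, 0))
  expect_equal(unname(which(gs$spr == 1.6, arr.ind = TRUE)[1, ]),
               c(7, 6, 6))
  # mass conserved up to boundary voxels (marker far from edge)
  expect_equal(sum(gs$spr), sum(g$spr), tolerance = 1e-6)
  ph <- phantom_fix("CTV_small")
  gp <- shift_geometry(ph$grid, c(0, 0.5, 0))
  inflow <- 22 * 44 * 44 * 0.001  # one boundary slab of air
  expect_lt(abs(sum(gp$spr) - sum(ph$grid$spr)), inflow)
})

test_that("displace_subvolume moves chords and handles edge cases", {
  # 2 cm water cube inside an air box
  g <- water_box(c(24, 24, 24), spacing = 0.5, spr = 0.001)
  m <- g$spr
  m[11:14, 11:14, 11:14] <- 1.0  # cube spans [-1,1] cm per axis
  g <- spr_grid(m, g$spacing, g$origin)
  region <- array(FALSE, dim = g$shape)
  region[11:14, 11:14, 11:14] <- TRUE

  expect_equal(displace_subvolume(g, region, c(0, 0, 0))$spr, g$spr)
  empty <- array(FALSE, dim = g$shape)
  expect_equal(displace_subvolume(g, empty, c(2, 0, 0))$spr, g$spr)

  gd <- displace_subvolume(g, region, c(2, 0, 0))
  # ray through the old location drops by the 2 cm chord, new location rises
  old_ray <- wet_along_ray(gd, c(0, 30, 0), c(0, -1, 0))
  new_ray <- wet_along_ray(gd, c(2.2, 30, 0), c(0, -1, 0))
  expect_lt(old_ray, 0.1)            # vacated: air only
  expect_gt(new_ray, 1.9)            # cube chord ~2 cm
  expect_error(displace_subvolume(g, region, c(20, 0, 0)), "outside")
})
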
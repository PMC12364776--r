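# synthetic one/two-spot problems exercise the objective machinery exactly
tiny_problem <- function(infl, objectives, ctv = 1, min_mu = 1e-6) {
  n <- ncol(infl)
  plan <- fake_plan(tibble::tibble(
    layer_id = 1L, dir_index = 1L, angle = 0, energy = 100,
    u = seq_len(n) * 0.6, v = 0, mu = 0.1, is_st = FALSE), angles = 0)
  structure(list(
    plan = plan, objectives = objectives,
    roi_nom = list(CTV = ctv, OAR = integer(0),
                   External = seq_len(nrow(infl))),
    roi_rob = list(CTV = ctv, OAR = integer(0)),
    shell = setdiff(seq_len(nrow(infl)), ctv),
    dist_ctv = rep(1, nrow(infl)),
    infl_nom = infl, infl_rob = list(), scenarios = list(),
    min_spot_mu = min_mu
  ), class = "optimization_problem")
}

uniform_only <- function(d0 = 60, w = 1) {
  tibble::tibble(kind = "uniform", roi = "CTV", dose = d0, dose_low = NA,
                 volume = NA, eud_a = NA, dist_l = NA, weight = w,
                 robust = FALSE)
}

test_that("objective term values match closed forms", {
  prob <- tiny_problem(Matrix::Matrix(1, 1, 1, sparse = TRUE),
                       default_objectives())
  ctx <- list(shell = 1L, dist_ctv = 0.5)
  # uniform term is zero at the prescription
  t_u <- default_objectives()[1, ]
  expect_equal(starc:::term_eval(t_u, rep(60, 5), list(CTV = 1:5))$value, 0)
  # max EUD with A = 1: weight * (mean - limit)^2
  t_e <- default_objectives()[4, ]
  expect_equal(starc:::term_eval(t_e, rep(6, 4), list(OAR = 1:4))$value,
               3 * (6 - 4)^2)
  # fall-off reference dose at 0.5 cm from the CTV: 60 -> 0 over 1 cm = 30
  t_f <- default_objectives()[5, ]
  v <- starc:::term_eval(t_f, 40, list(), ctx = ctx)$value
  expect_equal(v, 0.5 * (40 - 30)^2)
  # below the reference: no penalty
  expect_equal(starc:::term_eval(t_f, 25, list(), ctx = ctx)$value, 0)
})

test_that("EUD matches the generalized mean and its A-monotonicity", {
  expect_equal(eud(c(2, 4), 1), 3)
  expect_equal(eud(rep(7, 10), 15), 7)
  expect_gt(eud(c(10, 48), 15), eud(c(10, 48), 1))
  expect_lt(abs(eud(c(10, 48), 15) - 48), abs(eud(c(10, 48), 1) - 48))
  expect_error(eud(c(1, 2), 0), "unsupported")
})

test_that("single-spot problem recovers the analytic weight", {
  a <- 0.7  # dose per MU at the single voxel
  prob <- tiny_problem(Matrix::Matrix(a, 1, 1, sparse = TRUE),
                       uniform_only(60))
  res <- optimize_weights(prob, max_iter = 100)
  expect_equal(res$weights, 60 / a, tolerance = 1e-3)
})

test_that("two identical spots split the weight symmetrically", {
  a <- Matrix::Matrix(c(0.5, 0.5), 1, 2, sparse = TRUE)
  prob <- tiny_problem(a, uniform_only(60))
  res <- optimize_weights(prob, max_iter = 200)
  expect_equal(res$weights[1], res$weights[2], tolerance = 1e-6)
  expect_equal(sum(res$weights) * 0.5, 60, tolerance = 0.1)
})

test_that("layer filtering keeps the largest-MU layers with exemptions", {
  sp <- tibble::tibble(
    layer_id = rep(1:4, each = 2),
    dir_index = 1,
    angle = 0,
    energy = c(100, 100, 120, 120, 110, 110, 230, 230),
    u = 0, v = rep(c(0, 0.6), 4), mu = 0.1,
    is_st = rep(c(FALSE, FALSE, FALSE, TRUE), each = 2))
  plan <- fake_plan(sp, angles = 0)
  w <- c(2.5, 2.5, 1.5, 1.5, 0.5, 0.5, 9, 9)  # layer MU: 5, 3, 1, (ST 18)
  # keep 2 Bragg: the MU-1 layer is dropped, the ST layer is exempt
  kept <- filter_layers(plan, w, 2)
  expect_setequal(kept, c(1, 2, 4))
  # no-op when the budget covers everything
  expect_setequal(filter_layers(plan, w, 3), 1:4)
})

test_that("per-direction floor retains each direction's strongest layer", {
  sp <- tibble::tibble(
    layer_id = rep(1:4, each = 1),
    dir_index = c(1, 1, 1, 2),
    angle = c(0, 0, 0, 180),
    energy = c(100, 120, 140, 110),
    u = 0, v = 0, mu = 0.1, is_st = FALSE)
  plan <- fake_plan(sp, angles = c(0, 180))
  w <- c(5, 4, 3, 0.1)  # direction 2 is weakest overall
  kept <- filter_layers(plan, w, 2)
  expect_true(4 %in% kept)  # saved by the floor
  expect_true(1 %in% kept)
  expect_length(kept, 2)
})

test_that("spot filtering enforces the deliverability floor", {
  expect_equal(filter_spots(c(0.1, 0.0683, 0.05, 0)),
               c(TRUE, TRUE, FALSE, FALSE))
  sm <- smoke_plan("arc_st")
  w <- sm$result$weights
  expect_true(all(w[w > 0] >= 0.0683 - 1e-9))
})

test_that("clipping-with-reoptimization never loses to naive clipping", {
  # two CTV voxels; the unconstrained optimum (60, 24) puts spot 2 below a
  # floor of 30 MU, so it is removed and spot 1 must re-adjust upward
  a <- Matrix::Matrix(rbind(c(1.0, 0.0), c(0.8, 0.5)), sparse = TRUE)
  prob <- tiny_problem(a, uniform_only(60), ctv = 1:2, min_mu = 30)
  res <- optimize_weights(prob, max_iter = 200)
  active <- res$weights > 0
  expect_true(all(res$weights[active] >= 30 - 1e-9))
  # re-adjusted survivor: least squares over spot 1 alone, (60+48)/1.64
  expect_equal(res$weights[1], 108 / 1.64, tolerance = 1e-3)
  # naive clipping: unconstrained optimum with sub-floor spots zeroed
  wn <- c(60, 0)
  dose_of <- function(w) list(nominal = as.numeric(a %*% w),
                              scenarios = list())
  expect_lte(objective_value(dose_of(res$weights), prob),
             objective_value(dose_of(wn), prob) + 1e-9)
})

test_that("robust optimization scenario set has the declared composition", {
  sc <- robust_scenario_set()
  expect_length(sc, 9)
  labels <- vapply(sc, `[[`, character(1), "label")
  expect_equal(sum(labels == "nominal"), 1)
  shifts <- t(vapply(sc, `[[`, numeric(3), "shift"))
  norms <- sqrt(rowSums(shifts^2))
  expect_equal(sort(unique(round(norms, 10))), c(0, 0.3))
  expect_equal(sum(norms > 0), 6)
  scales <- vapply(sc, `[[`, numeric(1), "spr_scale")
  expect_setequal(round(scales[scales != 1], 3), c(0.965, 1.035))
})

test_that("objective history is non-increasing across accepted iterates", {
  sm <- smoke_plan("arc_st")
  for (h in sm$result$history) {
    expect_true(all(diff(h) <= 1e-9))
  }
})

test_that("shoot-through layers never worsen the fall-off objective", {
  # the optimized pure-Arc plan IS the re-optimized no-ST comparator under
  # the identical objective configuration
  st <- smoke_plan("arc_st")
  arc <- smoke_plan("arc")
  falloff_value <- function(sm) {
    ctx <- list(shell = sm$problem$shell, dist_ctv = sm$problem$dist_ctv)
    terms <- sm$problem$objectives
    sum(vapply(which(terms$kind == "falloff"), function(ti) {
      starc:::term_eval(terms[ti, ], sm$dose, sm$problem$roi_nom, ctx)$value
    }, numeric(1)))
  }
  expect_lte(falloff_value(st), falloff_value(arc) + 1e-9)
})
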
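#' Machine beam model
#'
#' Analytic model of a compact proton system with nozzle energy selection:
#' nominal energies 5-230 MeV, a Bragg-Kleeman range-energy law
#' `R = alpha * E^p` (alpha = 0.0022 cm/MeV^p, p = 1.77), Gaussian range
#' straggling `sigma_R = 0.012 * R^0.935` cm, an entrance spot size that grows
#' towards low energies (degrading in the nozzle broadens the beam):
#' `sigma_air(E) = 0.40 + 0.90 * (1 - (E - 5)/225)` cm, i.e. 0.40 cm at
#' 230 MeV up to 1.30 cm at 5 MeV, and in-patient multiple-Coulomb-scattering
#' growth `sigma_MCS(wed, R) = 0.021 * R * (wed/R)^1.5` cm (about 2.1% of the
#' range at end of range). Monitor units convert linearly to protons:
#' 0.0683 MU = 5.63e6 protons, the minimum deliverable spot weight. A constant
#' RBE of 1.1 is applied to all dose.
#'
#' The absolute dose calibration `calib` (Gy cm^3 per MU at unit
#' depth-dose density) is a single machine constant chosen so a typical
#' optimized phantom plan totals on the order of 1e3 MU; all plan-quality
#' metrics are relative, so it only sets the MU scale.
#'
#' @param n_levels Number of deliverable energy levels, spaced uniformly in
#'   range between R(5 MeV) and R(230 MeV).
#' @param calib Absolute dose calibration constant (Gy cm^3 / MU).
#' @return A `beam_model` list with constants and the energy table (a tibble
#'   with columns `energy`, `range`, `sigma_air`).
#' @export
beam_model <- function(n_levels = 64, calib = 6) {
  bm <- list(
    e_min = 5, e_max = 230,
    alpha = 0.0022, p = 1.77,
    straggling_coef = 0.012, straggling_exp = 0.935,
    sigma_mcs_coef = 0.021,
    min_spot_mu = 0.0683,
    protons_per_mu = 5.63e6 / 0.0683,
    rbe = 1.1,
    calib = calib,
    cutoff_sigma = 3.5,
    edge_sigma = 0.1
  )
  class(bm) <- "beam_model"
  bm$energy_table <- make_energy_table(n_levels, bm)
  bm$dd_cache <- new.env(parent = emptyenv())
  bm
}

#' @export
print.beam_model <- function(x, ...) {
  cat("<beam_model> ", x$e_min, "-", x$e_max, " MeV, ",
      nrow(x$energy_table), " levels, R(", x$e_max, ") = ",
      round(range_in_water(x$e_max, x), 2), " cm, min spot ",
      x$min_spot_mu, " MU, RBE ", x$rbe, "\n", sep = "")
  invisible(x)
}

#' Proton range in water
#'
#' Bragg-Kleeman law `R = alpha * E^p`. The maximum-energy range
#' (~33.3 cm at 230 MeV) exceeds any phantom chord, so shoot-through protons
#' always exit the patient with measurable residual range.
#'
#' @param E Energy in MeV, within machine limits.
#' @param bm A [beam_model()] (or default constants).
#' @return Range in cm of water.
#' @export
range_in_water <- function(E, bm = beam_model_constants()) {
  if (any(E < bm$e_min - 1e-9) || any(E > bm$e_max + 1e-9)) {
    stop("energy outside machine limits [", bm$e_min, ", ", bm$e_max,
         "] MeV", call. = FALSE)
  }
  bm$alpha * E^bm$p
}

#' Energy whose range in water equals `R` (inverse Bragg-Kleeman)
#' @param R Range in cm of water.
#' @param bm A [beam_model()].
#' @return Energy in MeV.
#' @export
energy_for_range <- function(R, bm = beam_model_constants()) {
  (R / bm$alpha)^(1 / bm$p)
}

# constants without the table, for the low-level functions
beam_model_constants <- function() {
  list(e_min = 5, e_max = 230, alpha = 0.0022, p = 1.77,
       straggling_coef = 0.012, straggling_exp = 0.935,
       sigma_mcs_coef = 0.021, min_spot_mu = 0.0683,
       protons_per_mu = 5.63e6 / 0.0683, rbe = 1.1)
}

#' Range straggling width
#' @param R Range in cm.
#' @param bm A [beam_model()].
#' @return Gaussian sigma (cm) of the range distribution.
#' @export
sigma_range <- function(R, bm = beam_model_constants()) {
  bm$straggling_coef * R^bm$straggling_exp
}

#' Entrance (in-air) spot sigma
#' @param E Energy in MeV.
#' @param bm A [beam_model()].
#' @return Sigma in cm at the patient surface.
#' @export
sigma_air <- function(E, bm = beam_model_constants()) {
  0.40 + 0.90 * (1 - (E - bm$e_min) / (bm$e_max - bm$e_min))
}

#' Build the deliverable energy table
#'
#' `n_levels` energies whose ranges are uniform between R(5 MeV) and
#' R(230 MeV), endpoints included; the binary range-shifter plates of the
#' nozzle give a dense discrete ladder which this table discretizes.
#'
#' @param n_levels Number of levels (>= 2).
#' @param bm Beam-model constants.
#' @return A tibble with `energy` (MeV), `range` (cm), `sigma_air` (cm),
#'   strictly increasing in range.
#' @export
make_energy_table <- function(n_levels = 64, bm = beam_model_constants()) {
  stopifnot(n_levels >= 2)
  rr <- seq(range_in_water(bm$e_min, bm), range_in_water(bm$e_max, bm),
            length.out = n_levels)
  ee <- energy_for_range(rr, bm)
  ee[1] <- bm$e_min
  ee[n_levels] <- bm$e_max
  tibble::tibble(energy = ee, range = rr, sigma_air = sigma_air(ee, bm))
}

#' Analytic depth-dose curve
#'
#' Bragg-Kleeman fluence-derivative profile, proportional to
#' `(R - z)^(1/p - 1)` for `z < R`, convolved with a Gaussian of width
#' `sigma_R` (range straggling) and normalized to unit integral over depth.
#' The integrable singularity at `z = R` is handled by exact per-bin
#' integration before smearing. For 230 MeV (R ~ 33.3 cm) the curve is a
#' quasi-flat plateau over any phantom chord <= 20 cm, the defining property
#' of shoot-through spots.
#'
#' @param E Energy in MeV.
#' @param bm A [beam_model()].
#' @param dz Depth sampling step (cm).
#' @return A list of class `depth_dose_curve` with `z` (cm), `dose`
#'   (1/cm, unit integral), `R`, `sigma_r`, `energy`.
#' @export
depth_dose <- function(E, bm = beam_model(), dz = 0.02) {
  R <- range_in_water(E, bm)
  sr <- sigma_range(R, bm)
  sr_eff <- max(sr, dz / 2)
  half <- ceiling(4 * sr_eff / dz)
  zmax <- R + 4 * sr + dz
  # extend below z = 0 so the straggling smear has no entrance edge artifact
  # ((R - z)^(q-1) continues naturally to negative depths)
  zb <- seq(-half * dz, zmax, by = dz)       # bin edges
  nb <- length(zb) - 1
  q <- 1 / bm$p                              # (R - z)^q antiderivative power
  anti <- function(z) {
    u <- pmax(R - z, 0)
    -u^q / q
  }
  mass <- anti(zb[-1]) - anti(zb[-length(zb)])  # integral of raw profile/bin
  zc <- (zb[-1] + zb[-length(zb)]) / 2
  # Gaussian smear of the bin masses onto the bin centres
  kern <- stats::dnorm(seq(-half, half) * dz, sd = sr_eff)
  kern <- kern / sum(kern)
  padded <- c(rep(0, half), mass, rep(0, half))
  sm <- as.numeric(stats::filter(padded, kern, sides = 2)[half + seq_len(nb)])
  keep <- zc > 0
  zc <- zc[keep]
  dose <- sm[keep] / dz
  dose[!is.finite(dose) | dose < 0] <- 0
  dose <- dose / (sum(dose) * dz)            # unit integral over depth
  structure(list(z = zc, dose = dose, R = R, sigma_r = sr, energy = E),
            class = "depth_dose_curve")
}

# cached lookup of depth-dose curves for tabulated energies
dd_curve_cached <- function(E, bm) {
  key <- format(E, digits = 12)
  if (!is.null(bm$dd_cache) && !is.null(bm$dd_cache[[key]])) {
    return(bm$dd_cache[[key]])
  }
  cur <- depth_dose(E, bm)
  if (!is.null(bm$dd_cache)) bm$dd_cache[[key]] <- cur
  cur
}

#' Lateral spot sigma at depth
#'
#' Quadrature sum of the entrance sigma and multiple-Coulomb-scattering
#' growth: `sigma = sqrt(sigma_air(E)^2 + (0.021 R (wed/R)^1.5)^2)`, with the
#' water-equivalent depth capped at the range.
#'
#' @param E Energy (MeV).
#' @param wed Water-equivalent depth (cm), >= 0.
#' @param bm A [beam_model()].
#' @return Sigma in cm.
#' @export
lateral_sigma <- function(E, wed, bm = beam_model_constants()) {
  stopifnot(all(wed >= 0))
  R <- range_in_water(E, bm)
  smcs <- bm$sigma_mcs_coef * R * (pmin(wed, R) / R)^1.5
  sqrt(sigma_air(E, bm)^2 + smcs^2)
}

#' MU / proton / charge conversions
#'
#' The machine meters dose in monitor units (MU); 0.0683 MU corresponds to
#' 5.63 million protons (the minimum deliverable spot weight), giving
#' ~8.243e7 protons per MU. Charge follows from the elementary charge.
#'
#' @param mu Monitor units (>= 0).
#' @param bm A [beam_model()].
#' @return `mu_to_protons`: proton count; `protons_to_charge`: charge in nC.
#' @export
mu_to_protons <- function(mu, bm = beam_model_constants()) {
  if (any(mu < 0)) stop("MU must be non-negative", call. = FALSE)
  mu * bm$protons_per_mu
}

#' @param n Proton count (>= 0).
#' @rdname mu_to_protons
#' @export
protons_to_charge <- function(n) {
  if (any(n < 0)) stop("proton count must be non-negative", call. = FALSE)
  n * 1.602e-10
}
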
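#' Run configuration
#'
#' Validated configuration for a full planning chain. Defaults reproduce the
#' study settings: 20 directions, prescription 60 GyRBE in 30 fractions,
#' margin factor 1.0 for uncollimated / 1.25 for collimated plans, an initial
#' Bragg-layer budget of 24 per direction (480 over the arc) filtered to 240,
#' and the nominal objective weights.
#'
#' @param values Named list (e.g. parsed from YAML) overriding defaults.
#' @return A validated `run_config` list.
#' @export
run_config <- function(values = list()) {
  def <- list(
    target = "CTV_small",
    spacing = 0.5,
    asymmetric = FALSE,
    n_directions = 20,
    angles = NULL,               # non-NULL for fixed-beam plans
    shoot_through = TRUE,
    collimated = FALSE,
    margin_factor = NULL,        # default depends on collimation
    spot_spacing = 0.6,
    prescription = 60,
    fractions = 30,
    initial_layers_per_direction = 24,
    final_layers = 240,
    falloff_weight_factor = 1,
    n_energy_levels = 64,
    max_iter = 200,
    tol = 1e-6,
    seed = 17,
    robust = TRUE,
    output_dir = "starc_out"
  )
  unknown <- setdiff(names(values), names(def))
  if (length(unknown) > 0) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg <- utils::modifyList(def, values)
  if (is.null(cfg$margin_factor)) {
    cfg$margin_factor <- if (cfg$collimated) 1.25 else 1.0
  }
  stopifnot(cfg$spacing > 0, cfg$spacing <= 1,
            cfg$n_directions >= 1, cfg$prescription > 0,
            cfg$initial_layers_per_direction >= 1,
            cfg$spot_spacing > 0, cfg$max_iter >= 1)
  if (!cfg$target %in% ctv_names) {
    stop("config: unknown target '", cfg$target, "'", call. = FALSE)
  }
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param path YAML file to load.
#' @export
read_config <- function(path) {
  run_config(yaml::read_yaml(path))
}

#' Run the full planning chain
#'
#' Deterministic end-to-end run: build the phantom, assemble the plan (arc or
#' fixed beams, optional shoot-through layers and collimation), optimize the
#' spot weights against the robust objective set, evaluate plan metrics and
#' delivery time, and optionally write artifacts (grid NRRD, plan JSON,
#' metrics report). Same config and seed give byte-identical metrics JSON.
#'
#' @param config A [run_config()] (or list / YAML path).
#' @param write Write artifacts to `config$output_dir`?
#' @param robustness Include the 28-scenario worst-case evaluation?
#' @return List with `phantom`, `plan` (optimized), `result`, `metrics`,
#'   `time`.
#' @export
run_full_chain <- function(config = run_config(), write = FALSE,
                           robustness = TRUE) {
  if (is.character(config)) config <- read_config(config)
  if (!inherits(config, "run_config")) config <- run_config(config)
  set.seed(config$seed)

  bm <- beam_model(n_levels = config$n_energy_levels)
  phantom <- build_phantom(phantom_spec(asymmetric = config$asymmetric),
                           spacing = config$spacing,
                           target_choice = config$target)
  angles <- if (!is.null(config$angles)) sort(config$angles) else
    make_arc_directions(config$n_directions)
  plan <- build_plan(phantom, bm, angles = angles,
                     n_layers_per_direction =
                       config$initial_layers_per_direction,
                     margin_factor = config$margin_factor,
                     collimated = config$collimated,
                     spot_spacing = config$spot_spacing,
                     prescription = config$prescription,
                     fractions = config$fractions)
  if (config$shoot_through) plan <- add_st_layer(plan, phantom, bm)

  objectives <- default_objectives(config$prescription,
                                   config$falloff_weight_factor)
  scen <- if (config$robust) robust_scenario_set() else list()
  problem <- optimization_problem(phantom, plan, bm, objectives, scen)
  result <- optimize_weights(problem, final_layers = config$final_layers,
                             max_iter = config$max_iter, tol = config$tol)
  plan <- result$plan
  metrics <- plan_metrics(phantom, plan, bm, infl_nom = problem$infl_nom,
                          robustness = robustness)
  tb <- plan_time(plan, time_model())

  if (write) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    write_grid(phantom$grid, file.path(config$output_dir, "spr_grid.nrrd"))
    for (nm in names(phantom$rois)) {
      write_grid(spr_grid(array(as.numeric(phantom$rois[[nm]]),
                                dim = phantom$grid$shape),
                          phantom$grid$spacing, phantom$grid$origin),
                 file.path(config$output_dir,
                           paste0("mask_", gsub("[^A-Za-z0-9_.]", "_", nm),
                                  ".nrrd")))
    }
    write_plan(plan, file.path(config$output_dir, "plan.json"))
    write_report(metrics, file.path(config$output_dir, "metrics"))
  }
  list(phantom = phantom, plan = plan, result = result, metrics = metrics,
       time = tb, beam_model = bm, problem = problem, config = config)
}
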
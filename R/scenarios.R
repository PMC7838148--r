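#' Reproducible estimation scenarios
#'
#' A scenario bundles everything needed to reproduce one end-to-end
#' tumor-extent estimation: the grid, the diffusion field specification,
#' model parameters, time controls, the pinning time at which the forward
#' solution is thresholded into the internal Dirichlet constraint, and the
#' random seed.  Scenarios are plain serializable lists; re-running a
#' serialized scenario reproduces its outputs exactly (the linear solver is
#' a deterministic sparse direct solve).
#'
#' @name scenarios
NULL

#' Built-in scenario fixtures
#'
#' Returns a named scenario with the standard defaults of the validation
#' studies:
#' * `"1d-homogeneous"` — nondimensional 1D Fisher-KPP, domain `[0, 200]`
#'   with 1000 elements, `rho = 1`, `D = 1`, penalty magnitude
#'   \eqn{5/\sqrt 6}, end time 20, centered Gaussian start.
#' * `"1d-random"` — as above with a randomly perturbed isotropic field
#'   (`beta = 0.8`).
#' * `"2d-butterfly"` — 200 x 200 domain, banded sinusoidal diffusivity,
#'   Gaussian start at (50, 50), end time 20.
#' * `"3d-synthetic"` — small 3D volume with a procedurally generated
#'   banded-anisotropy SPD tensor field (synthetic stand-in for a
#'   DTI-derived diffusivity).
#' * `"3d-external"` — dimensional parameters for a real DTI volume
#'   (`alpha = 5e-12`, `rho = 1e-6` per second, `v = 2.04e-6` m/s, 90 days);
#'   requires a user-supplied tensor volume via `overrides$tensor_path`.
#'
#' @param kind Scenario name.
#' @param overrides Named list of fields to override (e.g. `cells`, `dt`,
#'   `seed`).
#' @return An object of class `scenario`.
#' @export
#' @examples
#' make_fixture("1d-homogeneous")$params$v_mag  # 5/sqrt(6)
make_fixture <- function(kind, overrides = list()) {
  base <- switch(kind,
    "1d-homogeneous" = list(
      name = kind, extents = 200, cells = 1000L,
      field = list(type = "homogeneous", D = 1),
      rho = 1, v_mag = fisher_wave_speed(), theta = 0.16, alpha = 1,
      t_end = 20, dt = 0.1, pin_time = 20,
      ic = list(center = 100, sd = 1, amplitude = 1),
      seed = 1L),
    "1d-random" = list(
      name = kind, extents = 200, cells = 1000L,
      field = list(type = "random", beta = 0.1),
      rho = 1, v_mag = fisher_wave_speed(), theta = 0.16, alpha = 1,
      t_end = 20, dt = 0.1, pin_time = 20,
      ic = list(center = 100, sd = 1, amplitude = 1),
      seed = 1L),
    "2d-butterfly" = list(
      name = kind, extents = c(200, 200), cells = c(100L, 100L),
      field = list(type = "butterfly", amplitude = 0.9, modes = 3),
      rho = 1, v_mag = fisher_wave_speed(), theta = 0.16, alpha = 1,
      t_end = 20, dt = 0.1, pin_time = 20,
      ic = list(center = c(50, 50), sd = 2, amplitude = 1),
      seed = 1L),
    "3d-synthetic" = list(
      name = kind, extents = c(40, 40, 40), cells = c(20L, 20L, 20L),
      field = list(type = "synthetic-anisotropic", contrast = 1.5, bands = 2),
      rho = 1, v_mag = fisher_wave_speed(), theta = 0.16, alpha = 1,
      t_end = 6, dt = 0.2, pin_time = 6,
      ic = list(center = c(20, 20, 20), sd = 4, amplitude = 1),
      seed = 1L),
    "3d-external" = list(
      name = kind, extents = NULL, cells = NULL,
      field = list(type = "external", tensor_path = NULL, layout = "upper"),
      rho = 1e-6, v_mag = 2.04e-6, theta = 0.16, alpha = 5e-12,
      t_end = 90 * 86400, dt = 86400, pin_time = 90 * 86400,
      ic = list(center = c(0.09, 0.12, 0.05), sd = 0.005, amplitude = 1),
      seed = 1L),
    stop(sprintf("unknown scenario kind '%s'", kind), call. = FALSE)
  )
  for (nm in names(overrides)) base[[nm]] <- overrides[[nm]]
  structure(base, class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf("scenario '%s': %s field, rho = %g, v = %g, theta = %g, pin at t = %g\n",
              x$name, x$field$type, x$rho, x$v_mag, x$theta, x$pin_time))
  invisible(x)
}

#' Serialize / deserialize a scenario
#'
#' @param scenario A `scenario`.
#' @param path File path; when omitted, the JSON string is returned.
#' @return `scenario_to_json`: the path or JSON string;
#'   `scenario_from_json`: a `scenario`.
#' @export
scenario_to_json <- function(scenario, path = NULL) {
  stopifnot(inherits(scenario, "scenario"))
  js <- jsonlite::toJSON(unclass(scenario), auto_unbox = TRUE, digits = NA,
                         null = "null")
  if (is.null(path)) return(as.character(js))
  writeLines(as.character(js), path)
  invisible(path)
}

#' @rdname scenario_to_json
#' @param json JSON string or file path to read.
#' @export
scenario_from_json <- function(json) {
  lst <- if (file.exists(json)) jsonlite::fromJSON(json) else jsonlite::fromJSON(json)
  lst$cells <- as.integer(lst$cells)
  structure(lst, class = "scenario")
}

# materialize the tensor field a scenario describes
scenario_field <- function(scenario, grid) {
  fs <- scenario$field
  switch(fs$type,
    "homogeneous" = homogeneous_field(grid, fs$D %||% 1),
    "random" = random_isotropic_field(grid, fs$beta, scenario$seed),
    "butterfly" = butterfly_field(grid, fs$amplitude %||% 0.9, fs$modes %||% 3),
    "synthetic-anisotropic" = synthetic_anisotropic_field(
      grid, fs$contrast %||% 1.5, fs$bands %||% 2),
    "external" = {
      if (is.null(fs$tensor_path)) {
        stop("external scenario requires overrides$field$tensor_path",
             call. = FALSE)
      }
      scale_dti(read_tensor_nifti(fs$tensor_path, grid,
                                  layout = fs$layout %||% "upper"),
                scenario$alpha)
    },
    stop(sprintf("unknown field type '%s'", fs$type), call. = FALSE)
  )
}

#' Run the full estimation pipeline for a scenario
#'
#' Executes the procedure mimicking the clinical situation: (1) forward-run
#' the growth model from a small Gaussian to the pinning time (simulated
#' carciogenesis, the fictional gold standard); (2) threshold the forward
#' solution at the visibility threshold and extract the internal Dirichlet
#' shell (the segmented scan); (3) solve the stationary wave-pinned problem
#' localized by that constraint; (4) compare estimate and reference via the
#' level-set sweep, the gradient-cloud diagnostic and the Péclet screen.
#'
#' @param scenario A `scenario` from [make_fixture()].
#' @param levels Thresholds for the level-set sweep (default
#'   `c(1e-4, 1e-3, 1e-2, 0.16)`).
#' @param output_dir Optional directory; when given, fields (VTK), metrics
#'   (CSV) and the run record (JSON) are written there.
#' @return An object of class `run_record`: the scenario, `grid`, `forward`
#'   (a `forward_solution`), `constraints`, `stationary`
#'   (a `stationary_solution`), `metrics` (level-set sweep data.frame),
#'   `gradient_cloud` summary, `peclet` summary, `signed_error` nodal field,
#'   and file `paths` when written.
#' @export
run_estimation <- function(scenario, levels = c(1e-4, 1e-3, 1e-2, 0.16),
                           output_dir = NULL) {
  stopifnot(inherits(scenario, "scenario"))
  grid <- build_grid(scenario$extents, scenario$cells)
  field <- scenario_field(scenario, grid)
  params <- model_params(rho = scenario$rho, v_mag = scenario$v_mag,
                         theta = scenario$theta, alpha = scenario$alpha)
  controls <- time_controls(t_end = scenario$pin_time, dt = scenario$dt)
  init <- gaussian_ic(grid, center = scenario$ic$center,
                      sd = scenario$ic$sd, amplitude = scenario$ic$amplitude)

  sys <- assemble(grid, field)
  fwd <- solve_forward(grid, field, params, init, controls, system = sys)
  if (!fwd$report$converged) {
    stop(sprintf("forward stage failed: %s", fwd$report$failure), call. = FALSE)
  }
  u_ref <- fwd$states[, ncol(fwd$states)]

  # pin the full visible region so level-set comparisons below theta read
  # the outside margin, not the (unread) interior of the segmentation
  cons <- withCallingHandlers(
    extract_constraints(grid, u_ref, scenario$theta, interior = TRUE),
    warning = function(w) invokeRestart("muffleWarning"))
  trivial <- length(cons$indices) == 0

  stat <- solve_stationary(grid, field, params, cons, system = sys)
  if (!stat$report$converged) {
    stop(sprintf("stationary stage failed: %s", stat$report$failure),
         call. = FALSE)
  }

  sweep_df <- levelset_sweep(grid, u_ref, stat$u, levels = levels)
  cloud <- gradient_cloud(grid, u_ref)
  drift <- if (any(grid$cells >= 2)) tensor_divergence(field) else NULL
  tau <- peclet_field(field, drift)
  signed_err <- stat$u - u_ref

  rec <- structure(list(
    scenario = scenario, grid = grid,
    forward = fwd, constraints = cons, stationary = stat,
    metrics = sweep_df,
    gradient_cloud = list(max_deviation = cloud$max_deviation,
                          mean_deviation = cloud$mean_deviation),
    peclet = list(max = max(tau), mean = mean(tau),
                  frac_below_0.3 = mean(tau < 0.3)),
    signed_error = signed_err,
    trivial = trivial,
    paths = NULL
  ), class = "run_record")

  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(
      forward = file.path(output_dir, "forward.vtk"),
      stationary = file.path(output_dir, "stationary.vtk"),
      metrics = file.path(output_dir, "levelset_metrics.csv"),
      cloud = file.path(output_dir, "gradient_cloud.csv"),
      record = file.path(output_dir, "run_record.json"))
    write_vtk(grid, list(u = u_ref), paths$forward)
    write_vtk(grid, list(u_s = stat$u, signed_error = signed_err),
              paths$stationary)
    utils::write.csv(sweep_df, paths$metrics, row.names = FALSE)
    utils::write.csv(cloud$samples, paths$cloud, row.names = FALSE)
    writeLines(jsonlite::toJSON(run_record_summary(rec), auto_unbox = TRUE,
                                digits = NA, null = "null", pretty = TRUE),
               paths$record)
    rec$paths <- paths
  }
  rec
}

# serializable summary of a run record (provenance + numeric summaries)
run_record_summary <- function(rec) {
  list(
    scenario = unclass(rec$scenario),
    package_version = as.character(utils::packageVersion("gliostat")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    forward_report = unclass(rec$forward$report),
    stationary_report = unclass(rec$stationary$report),
    n_constraints = length(rec$constraints$indices),
    metrics = rec$metrics,
    gradient_cloud = rec$gradient_cloud,
    peclet = rec$peclet,
    trivial = rec$trivial
  )
}

#' @export
print.run_record <- function(x, ...) {
  cat(sprintf("run_record '%s'%s\n", x$scenario$name,
              if (x$trivial) " [trivial: empty constraint set]" else ""))
  cat(sprintf("  pinned nodes: %d; Peclet max %.3g (%.0f%% below 0.3)\n",
              length(x$constraints$indices), x$peclet$max,
              100 * x$peclet$frac_below_0.3))
  print(x$metrics, row.names = FALSE)
  invisible(x)
}
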
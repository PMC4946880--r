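#' Run the scanning-FCS demo pipeline
#'
#' Executes the requested stages in dependency order on synthetic data:
#' `simulate` (raster + line scans), `rics`, `nandb`, `pcf`, `model`,
#' `sobol`, `calibrate`.  A failed stage is recorded and its dependents are
#' skipped.  All problem sizes default to a small smoke-test scale; pass a
#' `scan_config` for full-size runs.
#'
#' @param stages character vector of stage names (default all).
#' @param seed RNG seed used for every stochastic stage.
#' @param config `scan_config` for the raster stages.
#' @param out_dir optional directory; when given, stage results are written
#'   with [save_results()].
#' @param n_particles particles in the synthetic field.
#' @param D true diffusion coefficient of the synthetic species (um^2/s).
#' @param sobol_n Sobol design rows (kept small by default).
#' @return named list: per-stage results plus `status` (one of `"ok"`,
#'   `"failed"`, `"skipped"` per stage) and a `summary` list with one MI,
#'   one diffusion coefficient, one dimer percentage and one Sobol table
#'   when the corresponding stages ran.
#' @export
run_pipeline <- function(stages = c("simulate", "rics", "nandb", "pcf",
                                    "model", "sobol", "calibrate"),
                         seed = 1L,
                         config = scan_config(frame_count = 40L,
                                              image_size = 64L,
                                              n_lines = 2e4),
                         out_dir = NULL, n_particles = 120L, D = 6.33,
                         sobol_n = 32L) {
  known <- c("simulate", "rics", "nandb", "pcf", "model", "sobol",
             "calibrate")
  bad <- setdiff(stages, known)
  if (length(bad))
    stop("unknown stage name(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  deps <- list(simulate = character(0),
               rics = "simulate", nandb = "simulate", pcf = "simulate",
               model = character(0), sobol = "model", calibrate = "model")
  status <- stats::setNames(rep("skipped", length(known)), known)
  res <- list()
  run_stage <- function(name, fn) {
    need <- deps[[name]]
    if (length(need) && any(status[need] != "ok")) {
      status[name] <<- "skipped"
      return(invisible(NULL))
    }
    out <- try(fn(), silent = TRUE)
    if (inherits(out, "try-error")) {
      status[name] <<- paste("failed:", attr(out, "condition")$message)
    } else {
      status[name] <<- "ok"
      res[[name]] <<- out
    }
  }
  psf <- psf_model()
  if ("simulate" %in% stages) run_stage("simulate", function() {
    set.seed(seed)
    geom <- default_geometry(config, psf, "raster")
    sp <- species_spec("monomer", D, 0.5, count = n_particles)
    tr <- simulate_particles(sp, geom,
                             total_time = config$frame_count *
                               frame_time(config),
                             dt = config$line_time * 1e-3)
    raster <- render_raster_series(tr, psf, config, background_rate = 0.1)
    # line scan across a permeable cell wall of finite thickness
    lcfg <- scan_config(pixel_size = 0.1, pixel_dwell = config$pixel_dwell,
                        line_time = 0.5, image_size = 32L,
                        line_length = 32L, n_lines = config$n_lines)
    wall_x <- 16 * lcfg$pixel_size
    walls <- data.frame(position = wall_x + c(-0.15, 0.15), p_f = 1,
                        p_r = 1)
    lgeom <- geometry_spec(xlim = c(-6.4, 6.4), ylim = c(-0.75, 0.75),
                           zlim = c(-2.25, 2.25), walls = walls,
                           periodic_x = TRUE)
    lsp <- species_spec("monomer", D, 8, count = 90L)
    lines <- synthesize_lines(lsp, psf, lcfg, geometry = lgeom,
                              background_rate = 0.05)
    list(raster = raster, lines = lines)
  })
  if ("rics" %in% stages) run_stage("rics", function() {
    flt <- subtract_moving_average(res$simulate$raster)
    fit_diffusion(compute_acf(flt), psf)
  })
  if ("nandb" %in% stages) run_stage("nandb", function() {
    set.seed(seed + 1L)
    s <- calibrate_sfactor(res$simulate$raster, min_pixels = 100L)
    brightness_map(res$simulate$raster, s_factor = s)
  })
  if ("pcf" %in% stages) run_stage("pcf", function() {
    set.seed(seed + 2L)
    lines <- res$simulate$lines
    wall <- locate_wall(lines$reference_before)
    calls <- vapply(c(5L, 7L, 9L), function(dr) {
      cols <- max(0, wall - dr - 1):min(31, wall + dr + 1)
      carpet <- pair_correlation(lines, dr, "forward", columns = cols)
      as.integer(detect_arch(carpet, wall, lines, n_perm = 100L))
    }, integer(1))
    movement_index(list(calls))
  })
  if ("model" %in% stages) run_stage("model", function() {
    traj <- simulate_model(default_model_params(), t_end = 36)
    list(trajectory = traj, metrics = steady_state_metrics(traj))
  })
  if ("sobol" %in% stages) run_stage("sobol", function() {
    set.seed(seed + 3L)
    sobol_replicate(N = sobol_n, t_end = 12, dt = 0.5)
  })
  if ("calibrate" %in% stages) run_stage("calibrate", function() {
    estimate_parameters(default_model_params())
  })
  summary <- list(
    MI = if (!is.null(res$pcf)) res$pcf$MI,
    D = if (!is.null(res$rics)) res$rics$D,
    dimer_pct = if (!is.null(res$calibrate))
      res$calibrate$achieved[["homodimer_pct"]],
    sobol = if (!is.null(res$sobol)) res$sobol$S_T)
  if (!is.null(out_dir)) {
    writable <- list(status = as.list(status), summary = list(
      MI = summary$MI, D = summary$D, dimer_pct = summary$dimer_pct))
    if (!is.null(summary$sobol)) writable$sobol_indices <- summary$sobol
    save_results(writable, out_dir, seed = seed)
  }
  c(res, list(status = status[stages], summary = summary))
}
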
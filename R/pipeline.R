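#' Run configuration
#'
#' A single self-describing configuration drives the end-to-end pipeline
#' (template, prepattern, simulation, analysis). Configurations are plain
#' nested lists, read from / written to YAML, and hashed (MD5 of the
#' canonical JSON serialization) so outputs can be traced to the exact
#' settings that produced them.
#'
#' Sections and defaults:
#' \describe{
#'   \item{template}{`type` ("disc" or "ring") with the generator arguments,
#'     or `path` to an existing tissue JSON file.}
#'   \item{prepattern}{`enabled` plus [prepattern_params()] fields and
#'     `rev_threshold` for the boundary mask.}
#'   \item{params}{[model_params()] fields.}
#'   \item{solver}{`t_end`, `rtol`, `atol`, `n_out`.}
#'   \item{noise}{`sd`, `seed` for the symmetry-breaking noise on `c_A`.}
#'   \item{analysis}{`rel_threshold` for peak detection, `window`/`tol` for
#'     the steady-state check.}
#' }
#'
#' @param ... named sections overriding the defaults (partial lists are
#'   merged field-wise).
#' @param path YAML file to read.
#' @param config a run config list.
#' @return `run_config` returns the merged config list (class `run_config`);
#'   `read_run_config`/`write_run_config` read and write YAML;
#'   `config_hash` returns the MD5 string.
#' @export
run_config <- function(...) {
  defaults <- list(
    template = list(type = "disc", n_cells = 400L, radius = 60,
                    seed = 1L, relaxation_steps = 30L),
    prepattern = list(enabled = TRUE, V_K = 1, V_R = 1, d_K = 1, d_R = 1,
                      K_K = 30, K_R = 25, n_K = 20, n_R = 20,
                      rev_orientation = "central", rev_threshold = 0.5),
    params = unclass(model_params()),
    solver = list(t_end = 1500, rtol = 1e-6, atol = 1e-9, n_out = 101L),
    noise = list(sd = 0, seed = 1L),
    analysis = list(rel_threshold = 0.5, window = 10L, tol = 1e-3)
  )
  over <- list(...)
  bad <- setdiff(names(over), names(defaults))
  if (length(bad)) stop("unknown config section(s): ", paste(bad, collapse = ", "))
  for (nm in names(over)) {
    defaults[[nm]] <- utils::modifyList(defaults[[nm]], as.list(over[[nm]]))
  }
  structure(defaults, class = "run_config")
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(run_config, raw)
}

#' @rdname run_config
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname run_config
#' @export
config_hash <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(unclass(config), tf, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tf))
}

build_template <- function(tpl) {
  if (!is.null(tpl$path)) {
    if (!file.exists(tpl$path)) stop("template path does not exist: ", tpl$path)
    return(read_tissue(tpl$path))
  }
  switch(tpl$type,
    disc = generate_disc_tissue(tpl$n_cells, tpl$radius, seed = tpl$seed %||% 1L,
                                relaxation_steps = tpl$relaxation_steps %||% 30L),
    ring = generate_ring_tissue(tpl$n_cells, tpl$cell_volume %||% 1,
                                tpl$wall_area %||% 1),
    stop("unknown template type: ", tpl$type)
  )
}

#' Run the full pipeline for one configuration
#'
#' Template, prepattern equilibrium, simulation from zero initial
#' conditions, and pattern analysis, in one deterministic call. When
#' `out_dir` is given, writes `tissue.json`, `trajectory.csv` (tidy:
#' time, cell_id, A, P_tot, X), `pin_membrane.csv` (time, i, j, P_ij at the
#' sampled times), and `analysis.json` (peak statistics plus provenance:
#' config hash, package version, solver diagnostics). Identical
#' configurations produce byte-identical analysis files.
#'
#' @param config a [run_config()].
#' @param out_dir optional output directory (created if missing).
#' @param keep_pin write the per-wall membrane PIN1 CSV (largest output;
#'   default writes only the final sampled time, `"all"` writes every one,
#'   `"none"` skips it).
#' @return list with `tissue`, `prepattern` (or `NULL`), `mask`,
#'   `trajectory`, `peaks`, and `analysis` (the list serialized to JSON).
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL,
                         keep_pin = c("final", "all", "none")) {
  stopifnot(inherits(config, "run_config"))
  keep_pin <- match.arg(keep_pin)
  tissue <- build_template(config$template)

  prep <- NULL
  mask <- NULL
  if (isTRUE(config$prepattern$enabled)) {
    pp <- config$prepattern
    ppar <- prepattern_params(pp$V_K, pp$V_R, pp$d_K, pp$d_R,
                              pp$K_K, pp$K_R, pp$n_K, pp$n_R,
                              rev_orientation = pp$rev_orientation)
    prep <- prepattern_equilibrium(radial_coordinate(tissue, warn = FALSE), ppar)
    mask <- boundary_mask(prep, pp$rev_threshold)
  }

  mp <- do.call(model_params, config$params[names(config$params) %in% names(formals(model_params))])
  sol <- config$solver
  traj <- simulate_tissue(tissue, mp, prepattern = prep,
                          t_end = sol$t_end,
                          output_times = seq(0, sol$t_end, length.out = sol$n_out),
                          noise_sd = config$noise$sd, noise_seed = config$noise$seed,
                          rtol = sol$rtol, atol = sol$atol)

  fs <- final_state(traj)
  ss <- steady_state(traj, window = config$analysis$window, tol = config$analysis$tol)
  converged <- !inherits(ss, "not_converged")
  peaks <- detect_peaks(fs, tissue, rel_threshold = config$analysis$rel_threshold)
  score <- if (length(peaks$peak_idx) > 0L && !is.null(mask)) {
    boundary_restriction_score(peaks, mask)
  } else NULL
  gap_cv <- if (length(peaks$peak_idx) >= 2L) peak_spacing(peaks, tissue)$gap_cv else NULL
  drift <- tryCatch(
    conservation_report(trajectory = traj, tissue = tissue, params = mp),
    undefined_conservation = function(e) list(drift = NA, informational = TRUE)
  )

  analysis <- list(
    n_peaks = length(peaks$peak_cells),
    peak_cells = peaks$peak_cells,
    peak_to_trough = peak_to_trough(fs),
    boundary_score = score,
    gap_cv = gap_cv,
    peak_radius_iqr = if (length(peaks$peak_idx) > 0L) peak_radii(peaks, tissue)$iqr else NULL,
    conservation_drift = drift$drift,
    conservation_informational = drift$informational,
    converged = converged,
    solver_stats = lapply(traj$solver_stats, as.numeric),
    provenance = list(config_hash = config_hash(config),
                      package_version = as.character(utils::packageVersion("auxinpattern")),
                      seed = config$template$seed %||% NA,
                      noise_seed = config$noise$seed)
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_tissue(tissue, file.path(out_dir, "tissue.json"))
    nt <- length(traj$times)
    ids <- tissue$cells$id
    tidy <- data.frame(
      time = rep(traj$times, times = length(ids)),
      cell_id = rep(ids, each = nt),
      A = as.vector(traj$A), P_tot = as.vector(traj$P_tot), X = as.vector(traj$X)
    )
    utils::write.csv(tidy, file.path(out_dir, "trajectory.csv"), row.names = FALSE)
    if (keep_pin != "none") {
      times_out <- if (keep_pin == "all") seq_len(nt) else nt
      pin <- do.call(rbind, lapply(times_out, function(k) {
        st <- state_at(traj, traj$times[k])
        pm <- pin_membrane(st, tissue, mp)
        cbind(time = traj$times[k], pm)
      }))
      utils::write.csv(pin, file.path(out_dir, "pin_membrane.csv"), row.names = FALSE)
    }
    jsonlite::write_json(analysis, file.path(out_dir, "analysis.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  invisible(list(tissue = tissue, prepattern = prep, mask = mask,
                 trajectory = traj, peaks = peaks, analysis = analysis))
}

#' Paired boundary-restriction experiment
#'
#' The package's headline in-silico experiment: one disc template, two
#' simulations with identical transport parameters — one without any
#' KAN/REV prepattern (auxin maxima self-organize anywhere) and one with the
#' equilibrium KAN/REV pattern repressing the polarizing signal (maxima
#' confined to the boundary annulus). Reports peak counts, the boundary
#' restriction score of the prepatterned run, and the radial spread (IQR)
#' of peak positions in both.
#'
#' @param n_cells,radius,seed disc-template arguments.
#' @param params [model_params()] for both runs.
#' @param prepattern_pars [prepattern_params()] for the patterned run.
#' @param rev_threshold REV cutoff for the boundary mask.
#' @param t_end,n_out simulation horizon and number of samples.
#' @param rel_threshold peak-detection threshold.
#' @param out_dir optional directory: writes `figure_off.png` /
#'   `figure_on.png` panels and `report.json`.
#' @return list with components `tissue`, `mask`, `off` and `on` (each:
#'   trajectory, peaks) and `report` (named numbers).
#' @export
figure9_experiment <- function(n_cells = 400L, radius = 60, seed = 1L,
                               params = model_params(),
                               prepattern_pars = prepattern_params(),
                               rev_threshold = 0.5,
                               t_end = 1500, n_out = 101L,
                               rel_threshold = 0.5,
                               out_dir = NULL) {
  tissue <- generate_disc_tissue(n_cells, radius, seed = seed)
  r <- radial_coordinate(tissue, warn = FALSE)
  prep <- prepattern_equilibrium(r, prepattern_pars)
  mask <- boundary_mask(prep, rev_threshold)
  times <- seq(0, t_end, length.out = n_out)

  run_one <- function(prepattern) {
    traj <- simulate_tissue(tissue, params, prepattern = prepattern,
                            t_end = t_end, output_times = times)
    fs <- final_state(traj)
    peaks <- detect_peaks(fs, tissue, rel_threshold = rel_threshold)
    list(trajectory = traj, state = fs, peaks = peaks,
         converged = !inherits(steady_state(traj), "not_converged"))
  }
  off <- run_one(NULL)
  on <- run_one(prep)

  report <- list(
    n_peaks_off = length(off$peaks$peak_cells),
    n_peaks_on = length(on$peaks$peak_cells),
    peak_to_trough_off = peak_to_trough(off$state),
    peak_to_trough_on = peak_to_trough(on$state),
    boundary_score_on = if (length(on$peaks$peak_idx)) boundary_restriction_score(on$peaks, mask) else NA_real_,
    boundary_score_off = if (length(off$peaks$peak_idx)) boundary_restriction_score(off$peaks, mask) else NA_real_,
    peak_radius_iqr_off = if (length(off$peaks$peak_idx)) peak_radii(off$peaks, tissue)$iqr else NA_real_,
    peak_radius_iqr_on = if (length(on$peaks$peak_idx)) peak_radii(on$peaks, tissue)$iqr else NA_real_
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (case in c("off", "on")) {
      res <- if (case == "off") off else on
      grDevices::png(file.path(out_dir, sprintf("figure_%s.png", case)),
                     width = 800, height = 800)
      plot(tissue, values = res$state$A, peaks = res$peaks,
           mask = if (case == "on") mask else NULL,
           main = sprintf("auxin at t = %g (%s prepattern)", t_end,
                          if (case == "on") "with" else "no"))
      grDevices::dev.off()
    }
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(list(tissue = tissue, prepattern = prep, mask = mask,
                 off = off, on = on, report = report))
}
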
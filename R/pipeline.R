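## Orchestration: configuration, validation, the oversizing-rate sweep with
## stage caching, result export (CSV / VTU / STL) and a small CLI.

#' Default run configuration
#'
#' Every default equals the study's stated parameter set: idealized aorta
#' (50 mm arch radius, 400 mm descending, 30 mm ID, 2 mm wall), FET
#' (1.75 mm device wall, 50 mm skeleton, oversizing 0-30%), materials
#' (1 / 5 MPa, nu 0.48, rigid polyester), 100 mmHg, blood (0.004 Pa s,
#' 1050 kg/m^3), inlet 75 bpm / 53 ml.
#'
#' @param preset mesh/solver preset, `"coarse"` or `"medium"`.
#' @return nested configuration list (class `fet_config`).
#' @export
default_config <- function(preset = "coarse") {
  solver <- switch(preset,
    coarse = list(preset = "coarse", beam_ds = 2.5, n_deploy = 10,
                  n_release = 10, flow_n_s = 140, flow_n_e = 24,
                  dt = 5e-4, n_cycles = 2, tol_cyclic = 0.01,
                  mesh_n_theta = 12, mesh_ds = 2.5),
    medium = list(preset = "medium", beam_ds = 1.5, n_deploy = 15,
                  n_release = 15, flow_n_s = 220, flow_n_e = 34,
                  dt = 2.5e-4, n_cycles = 3, tol_cyclic = 0.01,
                  mesh_n_theta = 16, mesh_ds = 1.5),
    stop("unknown preset: ", preset))
  structure(list(
    geometry = list(arch_radius = 50, desc_length = 400, inner_diameter = 30,
                    wall_thickness = 2, arch_span = 180,
                    device_thickness = 1.75, skeleton_length = 50,
                    skeleton_arc_fraction = 0.5, graft_start_angle = 90,
                    branch_diameter = 10, branch_angles = c(100, 115, 130),
                    extension = 50),
    material = list(E_aorta_MPa = 1, E_skeleton_MPa = 5, nu = 0.48,
                    polyester_model = "rigid", E_polyester_MPa = 1780),
    load = list(pressure_mmHg = 100),
    fluid = list(mu = 0.004, rho = 1050),
    waveform = list(HR = 75, SV_ml = 53, systolic_fraction = 0.35,
                    reverse_fraction = 0),
    windkessel = list(mean_pressure_mmHg = 100,
                      splits = c(branch1 = 0.05, branch2 = 0.05,
                                 branch3 = 0.05, desc = 0.85),
                      pressure_window_mmHg = c(80, 120),
                      rp_fraction = 0.05),
    metrics = list(path_ds = 1, wss_threshold = 1.7, s_max = 100),
    solver = solver,
    rates = 0.15,
    seed = 1,
    output_dir = file.path(tempdir(), "fetsim-run")
  ), class = "fet_config")
}

#' Read / write a configuration (JSON)
#' @param path file path.
#' @return `fet_config`.
#' @export
read_config <- function(path) {
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  cfg$windkessel$splits <- unlist(cfg$windkessel$splits)
  structure(modifyList(unclass(default_config()), cfg), class = "fet_config")
}

#' @rdname read_config
#' @param config `fet_config` to write.
#' @export
write_config <- function(config, path) {
  cfg <- unclass(config)
  cfg$windkessel$splits <- as.list(cfg$windkessel$splits)  # keep names in JSON
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Validate a configuration
#'
#' Schema and physics sanity checks (positive lengths, Poisson ratio below
#' 0.5, four outlets, waveform integral equal to the stroke volume within
#' 0.1%, splits summing to one). Errors are collected and reported together.
#'
#' @param config `fet_config`.
#' @return list `valid` (logical), `errors` (character).
#' @export
validate_config <- function(config) {
  errs <- character(0)
  g <- config$geometry
  for (nm in c("arch_radius", "desc_length", "inner_diameter",
               "wall_thickness", "device_thickness", "skeleton_length"))
    if (!is.numeric(g[[nm]]) || g[[nm]] < 0)
      errs <- c(errs, paste0("geometry$", nm, " must be >= 0"))
  if (g$arch_span <= 0 || g$arch_span > 270)
    errs <- c(errs, "geometry$arch_span must lie in (0, 270]")
  m <- config$material
  if (m$nu <= 0 || m$nu >= 0.5)
    errs <- c(errs, "material$nu must lie in (0, 0.5)")
  if (m$E_aorta_MPa <= 0 || m$E_skeleton_MPa <= 0)
    errs <- c(errs, "material moduli must be positive")
  if (config$load$pressure_mmHg < 0)
    errs <- c(errs, "load$pressure_mmHg must be >= 0")
  if (config$fluid$mu <= 0 || config$fluid$rho <= 0)
    errs <- c(errs, "fluid constants must be positive")
  n_out <- length(g$branch_angles) + 1L
  if (n_out != length(config$windkessel$splits))
    errs <- c(errs, "outlet count mismatch between geometry and windkessel")
  if (n_out != 4L)
    errs <- c(errs, "expected 4 outlets (3 branches + descending)")
  if (abs(sum(config$windkessel$splits) - 1) > 1e-9)
    errs <- c(errs, "windkessel$splits must sum to 1")
  wf <- config$waveform
  if (wf$HR <= 0 || wf$SV_ml <= 0) {
    errs <- c(errs, "waveform HR and SV must be positive")
  } else {
    w <- make_waveform(wf$HR, wf$SV_ml * 1e-6, wf$systolic_fraction,
                       wf$reverse_fraction)
    integ <- integrate(function(t) w$Q_fun(t), 0, w$T,
                       subdivisions = 2000L)$value
    if (abs(integ - w$SV) / w$SV > 1e-3)
      errs <- c(errs, "waveform integral deviates from the stroke volume by > 0.1%")
  }
  if (any(config$rates < 0 | config$rates > 0.5))
    errs <- c(errs, "rates must lie in [0, 0.5]")
  list(valid = !length(errs), errors = errs)
}

config_objects <- function(config, rate) {
  g <- config$geometry; m <- config$material
  list(
    ap = aorta_params(g$arch_radius, g$desc_length, g$inner_diameter,
                      g$wall_thickness, g$arch_span),
    fp = fet_params(rate, g$device_thickness, g$skeleton_length,
                    g$inner_diameter, g$skeleton_arc_fraction,
                    g$graft_start_angle),
    mat = material_params(m$E_aorta_MPa, m$E_skeleton_MPa, m$nu,
                          m$polyester_model, m$E_polyester_MPa),
    load = load_case(config$load$pressure_mmHg),
    fluid = fluid_params(config$fluid$mu, config$fluid$rho),
    wf = make_waveform(config$waveform$HR, config$waveform$SV_ml * 1e-6,
                       config$waveform$systolic_fraction,
                       config$waveform$reverse_fraction))
}

config_hash <- function(...) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(list(...), auto_unbox = TRUE, digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the pipeline for one oversizing rate
#'
#' geometry -> structural (deploy + release) -> channel -> flow -> metrics.
#' Stages are cached on disk by configuration hash and re-used on re-runs.
#'
#' @param config `fet_config`.
#' @param rate oversizing rate (fraction).
#' @param stages subset of `c("geometry", "structural", "flow", "metrics")`.
#' @param write_fields write CSV/VTU/STL artifacts under the output dir.
#' @return list with stage results and a `manifest` entry.
#' @export
run_rate <- function(config, rate, stages = c("geometry", "structural",
                                              "flow", "metrics"),
                     write_fields = FALSE) {
  set.seed(config$seed)
  obj <- config_objects(config, rate)
  sv <- config$solver
  out_dir <- file.path(config$output_dir, sprintf("rate_%03d",
                                                  round(rate * 100)))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cache_dir <- file.path(config$output_dir, "cache")
  dir.create(cache_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(rate = rate, stages = list())
  res <- list(rate = rate)
  cached <- function(key, fun) {
    h <- config_hash(config[c("geometry", "material", "load", "fluid",
                              "waveform", "windkessel", "solver")],
                     rate, key)
    f <- file.path(cache_dir, paste0(key, "_", h, ".rds"))
    t0 <- Sys.time()
    if (file.exists(f)) {
      manifest$stages[[key]] <<- list(status = "cache-hit", hash = h)
      return(readRDS(f))
    }
    val <- fun()
    saveRDS(val, f)
    manifest$stages[[key]] <<- list(
      status = "computed", hash = h,
      seconds = as.numeric(difftime(Sys.time(), t0, units = "secs")))
    val
  }
  if ("geometry" %in% stages) {
    res$treated <- cached("geometry", function()
      assemble_treated(obj$ap, obj$fp, n_theta = sv$mesh_n_theta,
                       ds = sv$mesh_ds))
    if (write_fields) {
      write_stl(res$treated$aorta_lumen, file.path(out_dir, "lumen.stl"))
      write_vtu(res$treated$aorta_wall, file.path(out_dir, "wall.vtu"))
      write_stl(res$treated$skeleton, file.path(out_dir, "skeleton.stl"))
    }
  }
  if ("structural" %in% stages) {
    res$recoil <- cached("structural", function()
      solve_recoil(res$treated, obj$mat, obj$load,
                   control = list(beam_ds = sv$beam_ds,
                                  n_increments = sv$n_deploy),
                   release_increments = sv$n_release))
    pr2 <- stress_path_profile(res$recoil, "zeta2",
                               s_max = config$metrics$s_max,
                               ds = config$metrics$path_ds)
    pr1 <- stress_path_profile(res$recoil, "zeta1",
                               s_max = config$metrics$s_max,
                               ds = config$metrics$path_ds)
    res$sigma_profiles <- rbind(pr1, pr2)
    res$sigma_max_Pa <- attr(pr2, "sigma_max")
    res$phi_deg <- res$recoil$bending_angle
    if (write_fields) {
      write.csv(res$sigma_profiles,
                file.path(out_dir, "stress_profiles.csv"), row.names = FALSE)
      write_recoil_vtu(res$recoil, file.path(out_dir, "recoil_state.vtu"))
    }
  }
  if ("flow" %in% stages) {
    res$flow <- cached("flow", function() {
      chan <- recoiled_channel(res$recoil, extension = config$geometry$extension)
      bank <- calibrate_windkessel(
        obj$wf, config$windkessel$mean_pressure_mmHg,
        config$windkessel$splits, config$windkessel$pressure_window_mmHg,
        config$windkessel$rp_fraction)
      sol <- solve_transient(list(type = "channel", channel = chan,
                                  n_s = sv$flow_n_s, n_e = sv$flow_n_e),
                             obj$wf, bank, obj$fluid, dt = sv$dt,
                             n_cycles = sv$n_cycles, tol = sv$tol_cyclic)
      sol$channel <- chan
      sol
    })
    if (write_fields) {
      for (nm in names(res$flow$outlet_traces))
        write.csv(res$flow$outlet_traces[[nm]],
                  file.path(out_dir, paste0("outlet_", nm, ".csv")),
                  row.names = FALSE)
    }
  }
  if ("metrics" %in% stages) {
    wmg <- wall_metrics(res$flow, "greater")
    wml <- wall_metrics(res$flow, "lesser")
    res$wall_metrics <- list(greater = wmg, lesser = wml)
    sel <- wmg$s_edge_mm >= 0 & wmg$s_edge_mm <= config$metrics$s_max
    prof <- profile_path(data.frame(s = wmg$s_edge_mm[sel]),
                         wmg$wss_peak[sel], ds = config$metrics$path_ds)
    res$wss_profile <- prof
    res$wss_max_Pa <- attr(prof, "value_max")
    res$wss_argmax_mm <- attr(prof, "s_max_location")
    res$high_wss_mm <- high_wss_length(prof, config$metrics$wss_threshold)
    res$notch_mm2 <- res$flow$channel$notch$area_mm2
    res$notch <- notch_measure(res$flow$channel, flow = res$flow$field)
    if (write_fields) {
      write.csv(wmg, file.path(out_dir, "wall_metrics_greater.csv"),
                row.names = FALSE)
      write.csv(wml, file.path(out_dir, "wall_metrics_lesser.csv"),
                row.names = FALSE)
    }
  }
  res$manifest <- manifest
  res
}

#' Run the oversizing sweep
#'
#' @param config `fet_config` (uses `config$rates`).
#' @param write_fields write per-rate artifacts.
#' @return list `results` (per rate), `summary` (`sweep_summary`),
#'   `manifest`.
#' @export
run_sweep <- function(config, write_fields = FALSE) {
  vc <- validate_config(config)
  if (!vc$valid) stop("invalid config:\n  ", paste(vc$errors, collapse = "\n  "))
  results <- list()
  manifests <- list()
  for (rate in config$rates) {
    key <- sprintf("%.2f", rate)
    r <- run_rate(config, rate, write_fields = write_fields)
    results[[key]] <- r
    manifests[[key]] <- r$manifest
  }
  summ <- summarize_sweep(lapply(results, function(r)
    r[c("sigma_max_Pa", "phi_deg", "wss_max_Pa", "high_wss_mm",
        "notch_mm2")]))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(summ, file.path(config$output_dir, "sweep_summary.csv"),
            row.names = FALSE)
  jsonlite::write_json(
    list(config_hash = config_hash(unclass(config)), stages = manifests),
    file.path(config$output_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  list(results = results, summary = summ, manifest = manifests)
}

#' Command-line entry point
#'
#' Verbs: `validate`, `generate`, `recoil`, `flow`, `metrics`, `sweep`.
#' Common flags: `--config <path>`, `--preset coarse|medium`,
#' `--rates 0,0.15,0.30`, `--out <dir>`.
#'
#' @param args character vector (default: `commandArgs(trailingOnly=TRUE)`).
#' @return invisibly, the verb's result.
#' @export
fet_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) {
    cat("usage: fetsim <validate|generate|recoil|flow|metrics|sweep>",
        "[--config f] [--preset p] [--rates r1,r2] [--out dir]\n")
    return(invisible(NULL))
  }
  verb <- args[1]
  opt <- list(config = NULL, preset = "coarse", rates = NULL, out = NULL)
  i <- 2
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    if (!key %in% names(opt)) stop("unknown flag: ", args[i])
    opt[[key]] <- args[i + 1]; i <- i + 2
  }
  config <- if (!is.null(opt$config)) read_config(opt$config)
            else default_config(opt$preset)
  if (!is.null(opt$rates))
    config$rates <- as.numeric(strsplit(opt$rates, ",")[[1]])
  if (!is.null(opt$out)) config$output_dir <- opt$out
  res <- switch(verb,
    validate = {
      v <- validate_config(config)
      if (v$valid) cat("config valid\n")
      else cat("config INVALID:\n", paste(" -", v$errors, collapse = "\n"), "\n")
      v
    },
    generate = run_rate(config, config$rates[1], stages = "geometry",
                        write_fields = TRUE),
    recoil = run_rate(config, config$rates[1],
                      stages = c("geometry", "structural"),
                      write_fields = TRUE),
    flow = run_rate(config, config$rates[1],
                    stages = c("geometry", "structural", "flow"),
                    write_fields = TRUE),
    metrics = run_rate(config, config$rates[1], write_fields = TRUE),
    sweep = run_sweep(config, write_fields = TRUE),
    stop("unknown verb: ", verb))
  invisible(res)
}
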
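#' Validated experiment configuration
#'
#' A flat description of one figure-level analysis. Required key: `kind`,
#' one of `dose_response_det`, `bifurcation_1d`, `bifurcation_2d`,
#' `sensitivity`, `ssa_single`, `ssa_sweep`, `fdt_curves`,
#' `clamped_compare`. Optional keys: `params` (named overrides of
#' [circuit_params()] fields), `mode`, `parameter`, `range`, `resolution`,
#' `p_x`, `p_y`, `doses`, `reps`, `t_end`, `dt`, `seed`, `branch`,
#' `clamp_reference`, `out_dir`. Unknown keys are rejected. Configurations
#' round-trip losslessly through JSON.
#'
#' @param config A named list, or the path of a JSON file holding one.
#' @return The validated config (class `rc_config`).
#' @export
experiment_config <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  if (!is.list(config)) stop("config must be a named list or a JSON path")
  kinds <- c("dose_response_det", "bifurcation_1d", "bifurcation_2d",
             "sensitivity", "ssa_single", "ssa_sweep", "fdt_curves",
             "clamped_compare")
  allowed <- c("kind", "params", "mode", "parameter", "range", "resolution",
               "p_x", "p_y", "doses", "reps", "t_end", "dt", "seed",
               "branch", "clamp_reference", "out_dir")
  bad <- setdiff(names(config), allowed)
  if (length(bad))
    stop("invalid config keys: ", paste(bad, collapse = ", "))
  if (is.null(config$kind) || !(config$kind %in% kinds))
    stop("config$kind must be one of: ", paste(kinds, collapse = ", "))
  if (!is.null(config$params)) {
    bad <- setdiff(names(config$params), PARAM_NAMES)
    if (length(bad))
      stop("invalid parameter overrides: ", paste(bad, collapse = ", "))
  }
  if (!is.null(config$mode)) match_mode(config$mode)
  structure(config, class = "rc_config")
}

config_defaults <- function(config) {
  d <- list(mode = "shared", parameter = "I1", range = c(0, 2),
            resolution = 400, doses = seq(0, 2, length.out = 21),
            reps = 10, t_end = 5000, dt = 0.1, seed = 1,
            clamp_reference = "deterministic")
  for (nm in names(d)) if (is.null(config[[nm]])) config[[nm]] <- d[[nm]]
  config
}

#' Run one configured experiment and write its result bundle
#'
#' Dispatches on `config$kind`, writes all tables as CSV into
#' `config$out_dir` together with a JSON manifest (config, its md5 hash,
#' seeds, package version), and returns the result invisibly. Identical
#' config + seed reproduce byte-identical outputs.
#'
#' @param config An [experiment_config()] (list or JSON path).
#' @return Invisibly, a list with the computed result and the manifest.
#' @export
run_experiment <- function(config) {
  config <- experiment_config(config)
  config <- config_defaults(config)
  params <- do.call(circuit_params, as.list(config$params))
  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  wcsv <- function(df, name) {
    if (!is.null(out_dir))
      utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
  }
  res <- switch(
    config$kind,
    dose_response_det = {
      doses <- config$doses
      tab <- do.call(rbind, lapply(doses, function(d) {
        p <- update_params(params, I1 = d)
        ss <- find_steady_states(p, config$mode)
        do.call(rbind, lapply(ss, function(s)
          data.frame(I1 = d, m1 = s$state[["m1"]], p1 = s$state[["p1"]],
                     m2 = s$state[["m2"]], p2 = s$state[["p2"]],
                     stable = s$stable)))
      }))
      wcsv(tab, "dose_response.csv")
      tab
    },
    bifurcation_1d = {
      bd <- bifurcation_1d(params, config$mode, config$parameter,
                           config$range, resolution = config$resolution)
      wcsv(bd$points, "branches.csv")
      wcsv(bd$sn_points, "sn_points.csv")
      bd
    },
    bifurcation_2d = {
      b2 <- bifurcation_2d(params, config$mode, config$p_x, config$p_y)
      wcsv(b2$sn_curves, "sn_curves.csv")
      if (!is.null(out_dir))
        jsonlite::write_json(list(cusp = b2$cusp),
                             file.path(out_dir, "cusp.json"),
                             auto_unbox = TRUE, digits = NA)
      b2
    },
    sensitivity = {
      sr <- sensitivity_sn(params, config$mode)
      wcsv(sr, "sensitivity.csv")
      sr
    },
    ssa_single = {
      tr <- gillespie_run(params, config$mode, t_end = config$t_end,
                          seed = config$seed, dt = config$dt,
                          branch = config$branch)
      if (!is.null(out_dir))
        export_trajectory(tr, file.path(out_dir, "trajectory.csv"))
      tr
    },
    ssa_sweep = {
      sw <- dose_sweep(params, config$mode, config$doses,
                       reps = config$reps, t_end = config$t_end,
                       master_seed = config$seed, dt = config$dt,
                       summarise = "stationary")
      nc <- noise_dose_curves(sw)
      wcsv(nc$curves, "noise_curves.csv")
      wcsv(nc$peaks, "noise_peaks.csv")
      nc
    },
    fdt_curves = {
      tab <- fdt_noise_curves(params, config$mode, config$doses)
      wcsv(tab, "fdt_noise.csv")
      tab
    },
    clamped_compare = {
      sw <- dose_sweep(params, "shared", config$doses, reps = config$reps,
                       t_end = config$t_end, master_seed = config$seed,
                       dt = config$dt, summarise = "stationary",
                       clamp_reference = config$clamp_reference)
      nc <- noise_dose_curves(sw)
      wcsv(nc$curves, "noise_curves_clamped.csv")
      wcsv(nc$peaks, "noise_peaks_clamped.csv")
      nc
    })
  manifest <- list(kind = config$kind,
                   config = unclass(config),
                   config_md5 = config_hash(config),
                   seed = config$seed,
                   package_version = as.character(utils::packageVersion("rcnoise")))
  if (!is.null(out_dir))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  invisible(list(result = res, manifest = manifest))
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  cfg <- unclass(config)
  cfg <- cfg[order(names(cfg))]
  jsonlite::write_json(cfg, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}
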
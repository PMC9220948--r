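## Configuration loading and the file-producing run drivers used by the
## analysis scripts. A run config is a YAML (or JSON) file with a `bilayer`
## block mirroring the bilayer_params constructor arguments (explicit unit
## suffixes) and per-command blocks; every run writes a resolved-config
## copy next to its outputs so any artifact is reproducible from disk.

.BILAYER_KEYS <- c(
  "sigma_pN", "A_L_A2", "h_nm", "eps", "delta_V_mV", "d_min_nm", "A_tot_um2"
)
.TOP_KEYS <- c("bilayer", "sweep", "infer", "affinity", "output_dir", "seed")
.SWEEP_KEYS <- c("sigma_min_pN", "sigma_max_pN", "n_sigma")
.INFER_KEYS <- c(
  "R_obs_nm", "sigma_true_pN", "n_obs", "noise_sd_log",
  "sigma_bracket_pN", "n_boot", "conf"
)
.AFFINITY_KEYS <- c(
  "n_obs", "kd_min_M", "kd_max_M", "slope_tcr", "slope_stat5",
  "intercept_tcr", "intercept_stat5", "noise_sd"
)

.check_keys <- function(block, allowed, where) {
  bad <- setdiff(names(block), allowed)
  if (length(bad) > 0) {
    stop(
      "unknown key(s) in `", where, "`: ", paste(bad, collapse = ", "),
      call. = FALSE
    )
  }
}

.check_scalar_numbers <- function(block, where) {
  for (k in names(block)) {
    v <- block[[k]]
    if (!is.numeric(v) || length(v) > 2L || anyNA(v)) {
      stop(
        "key `", k, "` in `", where, "` must be numeric, got ",
        class(v)[1],
        call. = FALSE
      )
    }
  }
}

#' Read and validate a run configuration
#'
#' Loads a YAML or JSON run configuration. Unknown keys anywhere are
#' rejected (the costliest error class in a unit-heavy model is a silently
#' ignored misspelt parameter). The `bilayer` block mirrors the
#' [bilayer_params()] arguments with their unit suffixes (e.g. `A_L_A2:
#' 55`, `h_nm: 3.5`, `A_tot_um2: 20`); `sweep`, `infer` and `affinity`
#' blocks configure the respective drivers; missing values fall back to
#' the package defaults.
#'
#' @param path path to the YAML/JSON config file.
#' @return a `run_config` list with validated blocks.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("config must be a mapping", call. = FALSE)
  .check_keys(cfg, .TOP_KEYS, "top level")
  if (!is.null(cfg$bilayer)) {
    .check_keys(cfg$bilayer, .BILAYER_KEYS, "bilayer")
    .check_scalar_numbers(cfg$bilayer, "bilayer")
  }
  if (!is.null(cfg$sweep)) {
    .check_keys(cfg$sweep, .SWEEP_KEYS, "sweep")
    .check_scalar_numbers(cfg$sweep, "sweep")
  }
  if (!is.null(cfg$infer)) {
    .check_keys(cfg$infer, .INFER_KEYS, "infer")
    .check_scalar_numbers(cfg$infer, "infer")
  }
  if (!is.null(cfg$affinity)) {
    .check_keys(cfg$affinity, .AFFINITY_KEYS, "affinity")
    .check_scalar_numbers(cfg$affinity, "affinity")
  }
  if (!is.null(cfg$seed) &&
    (!is.numeric(cfg$seed) || length(cfg$seed) != 1L)) {
    stop("key `seed` must be a single integer", call. = FALSE)
  }
  structure(cfg, class = "run_config")
}

#' Build bilayer parameters from a config
#'
#' @param config a `run_config` (or plain list with a `bilayer` block).
#' @return a validated [bilayer_params()].
#' @export
params_from_config <- function(config) {
  b <- config$bilayer
  if (is.null(b)) b <- list()
  do.call(bilayer_params, b)
}

.resolve_out <- function(config, default_dir) {
  dir <- config$output_dir
  if (is.null(dir)) dir <- default_dir
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir
}

.write_resolved_config <- function(config, dir, stem) {
  path <- file.path(dir, paste0(stem, "_config.yaml"))
  yaml::write_yaml(unclass(config), path)
  path
}

#' Run a line-tension sweep and write its artifacts
#'
#' Drives [line_tension_sweep()] from a config: writes the sweep table as
#' CSV (`sigma_pN, R_star_nm, E_perim_J, E_elec_J, E_total_J, at_bound`),
#' the growth-law fit diagnostics as a JSON sidecar, and a resolved copy of
#' the configuration.
#'
#' @param config a `run_config`.
#' @return invisibly, a named list of the written file paths and the
#'   `sweep_result`.
#' @export
run_sweep <- function(config) {
  params <- params_from_config(config)
  s <- config$sweep
  if (is.null(s)) s <- list()
  lo <- if (is.null(s$sigma_min_pN)) 0.1 else s$sigma_min_pN
  hi <- if (is.null(s$sigma_max_pN)) 3 else s$sigma_max_pN
  n <- if (is.null(s$n_sigma)) 20L else as.integer(s$n_sigma)
  res <- line_tension_sweep(params, seq(lo, hi, length.out = n))
  dir <- .resolve_out(config, "results")
  csv <- file.path(dir, "sweep.csv")
  utils::write.csv(res$table, csv, row.names = FALSE)
  fit_json <- file.path(dir, "sweep_fit.json")
  jsonlite::write_json(
    list(
      growth_fit = res$growth_fit, comparison_fit = res$comparison_fit,
      n_interior = res$n_interior
    ),
    fit_json,
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  cfg <- .write_resolved_config(config, dir, "sweep")
  invisible(list(csv = csv, fit_json = fit_json, config = cfg, result = res))
}

#' Run an inverse line-tension recovery and write its artifacts
#'
#' Two modes. With `infer$R_obs_nm` set, the single observed radius is
#' inverted directly. Otherwise a synthetic experiment is run: noisy
#' radius observations are generated at `infer$sigma_true_pN` and the
#' tension recovered with a bootstrap interval. Results go to a JSON file
#' next to a resolved-config copy.
#'
#' @param config a `run_config`.
#' @return invisibly, list of written paths and the recovery result.
#' @export
run_infer <- function(config) {
  params <- params_from_config(config)
  inf <- config$infer
  if (is.null(inf)) inf <- list()
  bracket <- if (is.null(inf$sigma_bracket_pN)) c(0.01, 10) else inf$sigma_bracket_pN
  dir <- .resolve_out(config, "results")
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  if (!is.null(inf$R_obs_nm)) {
    sigma <- infer_line_tension(inf$R_obs_nm, params, bracket)
    out <- list(mode = "direct", R_obs_nm = inf$R_obs_nm, sigma_pN = sigma)
  } else {
    sigma_true <- if (is.null(inf$sigma_true_pN)) 1 else inf$sigma_true_pN
    n <- if (is.null(inf$n_obs)) 25L else as.integer(inf$n_obs)
    noise <- if (is.null(inf$noise_sd_log)) 0.1 else inf$noise_sd_log
    n_boot <- if (is.null(inf$n_boot)) 200L else as.integer(inf$n_boot)
    conf <- if (is.null(inf$conf)) 0.95 else inf$conf
    obs <- generate_noisy_domain_observations(
      sigma_true, params, n,
      noise_sd_log = noise, seed = seed
    )
    rec <- recover_line_tension_experiment(
      obs,
      sigma_bracket_pN = bracket, n_boot = n_boot, conf = conf
    )
    out <- list(
      mode = "synthetic", sigma_true_pN = sigma_true, n = n,
      noise_sd_log = noise, seed = seed,
      geomean_radius_nm = rec$geomean_radius_nm,
      sigma_hat_pN = rec$sigma_hat_pN,
      ci_lo_pN = rec$ci_pN[1], ci_hi_pN = rec$ci_pN[2],
      n_boot = n_boot, conf = conf
    )
  }
  json <- file.path(dir, "infer.json")
  jsonlite::write_json(out, json, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  cfg <- .write_resolved_config(config, dir, "infer")
  invisible(list(json = json, config = cfg, result = out))
}

#' Run the affinity-response stage and write its artifacts
#'
#' Generates a seeded affinity-phosphorylation dataset, fits both
#' responses on `log10(Kd)`, and writes the dataset CSV (with JSON
#' sidecar), the fit JSON and a resolved-config copy.
#'
#' @param config a `run_config`.
#' @return invisibly, list of written paths, the dataset and the fits.
#' @export
run_affinity <- function(config) {
  a <- config$affinity
  if (is.null(a)) a <- list()
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  args <- list(seed = seed)
  if (!is.null(a$n_obs)) args$n <- a$n_obs
  if (!is.null(a$kd_min_M) || !is.null(a$kd_max_M)) {
    args$kd_range_M <- c(
      if (is.null(a$kd_min_M)) 1e-9 else a$kd_min_M,
      if (is.null(a$kd_max_M)) 1e-5 else a$kd_max_M
    )
  }
  for (k in c(
    "slope_tcr", "slope_stat5", "intercept_tcr", "intercept_stat5",
    "noise_sd"
  )) {
    if (!is.null(a[[k]])) args[[k]] <- a[[k]]
  }
  ds <- do.call(generate_affinity_dataset, args)
  fit <- fit_affinity_response(ds)
  dir <- .resolve_out(config, "results")
  csv <- file.path(dir, "affinity_dataset.csv")
  write_affinity_dataset(ds, csv)
  json <- file.path(dir, "affinity_fit.json")
  jsonlite::write_json(fit, json, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  cfg <- .write_resolved_config(config, dir, "affinity")
  invisible(list(
    csv = csv, fit_json = json, config = cfg, dataset = ds, fit = fit
  ))
}
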
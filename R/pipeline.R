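# Pipeline runner: configuration handling, stage dispatch, run reports.

#' Read a run configuration
#'
#' Loads a YAML run configuration and applies overrides (override values
#' win over file values, which win over stage defaults).
#'
#' @param path Path to a YAML file with at least a `subcommand` field.
#' @param overrides Named list of settings replacing file values.
#' @return Named list (the merged configuration).
#' @export
read_run_config <- function(path, overrides = list()) {
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("configuration must be a YAML mapping",
                          call. = FALSE)
  utils::modifyList(cfg, overrides)
}

#' Read a one-number-per-line frequency file
#'
#' @param path Text file with one frequency (cm^-1) per line; blank lines
#'   and `#` comments are ignored.
#' @return Numeric vector of frequencies.
#' @export
read_frequencies <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- suppressWarnings(as.numeric(lines))
  if (anyNA(out))
    stop("non-numeric entry in frequency file ", path, call. = FALSE)
  out
}

.pipeline_subcommands <- c("thermo-cycle", "wigner", "kie", "rrkm",
                           "collide", "fit-threshold", "synth")
.stochastic_subcommands <- c("fit-threshold", "synth")

#' Run a named analysis stage and write a reproducible report
#'
#' Dispatches one of the pipeline subcommands, writes its output tables
#' (tab-separated, headers naming units) into the configured output
#' directory, and writes `summary.json` — a machine-readable record with
#' the package version, the full echoed configuration, its hash, and the
#' seed. Reruns with an identical configuration produce byte-identical
#' summaries. A plain-text `run.log` records stage progress.
#'
#' Subcommands and their settings:
#' \describe{
#'   \item{`thermo-cycle`}{`aip_neutral`, `aip_parent`, `acidities` (named
#'     list, eV), `basicity`: tabulates the charge-transfer endothermicity
#'     and per-site proton-transfer thresholds.}
#'   \item{`wigner`}{`imag_freqs` (cm^-1), `temperature` (default 298 K).}
#'   \item{`rrkm`}{`reactant_frequencies`, `ts_frequencies` (vectors or
#'     paths to one-per-line files), `e0_ev`, `e_grid_ev`, `grain_cm`
#'     (default 10), `e_max_cm`, `symmetry` (default 1): k(E) table.}
#'   \item{`kie`}{the `rrkm` settings twice, suffixed `_light`/`_heavy`,
#'     plus shared `e_grid_ev`: k-light, k-heavy and their ratio.}
#'   \item{`collide`}{`polarizability_a3`, `dipole_d`, `charge`,
#'     `temperature`, `e_grid_ev`, optional `xyz_ion`/`xyz_neutral` paths
#'     (+ `seed`, `n_orientations`): capture, hard-sphere and max cross
#'     sections per energy.}
#'   \item{`fit-threshold`}{`data` (curve table path), the
#'     [beam_conditions()] fields, `n_min`, `n_max`, `n_samples`, `seed`:
#'     fitted parameters, exponent scan and best-fit curve.}
#'   \item{`synth`}{`seed`, `sigma0`, `e0_ev`, `n`, the beam fields,
#'     `e_grid_ev`, `noise_cv`, `n_samples`, toy-species settings: writes
#'     a species config and a synthetic curve.}
#' }
#'
#' @param config Path to a YAML configuration or a named list. Must
#'   contain `subcommand` and `output_dir`; stochastic subcommands
#'   additionally require `seed`.
#' @return Invisibly, the summary list.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  if (!is.list(config)) stop("`config` must be a list or a YAML path",
                             call. = FALSE)
  sub <- config$subcommand
  if (is.null(sub) || !sub %in% .pipeline_subcommands)
    stop("unknown or missing subcommand; available: ",
         paste(.pipeline_subcommands, collapse = ", "), call. = FALSE)
  if (is.null(config$output_dir))
    stop("configuration error: missing key `output_dir`", call. = FALSE)
  if (sub %in% .stochastic_subcommands && is.null(config$seed))
    stop("configuration error: `seed` is mandatory for stochastic stage `",
         sub, "`", call. = FALSE)
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$output_dir, "run.log")
  log_lines <- sprintf("stage %s: started", sub)

  result <- switch(sub,
    "thermo-cycle"  = stage_thermo_cycle(config),
    "wigner"        = stage_wigner(config),
    "rrkm"          = stage_rrkm(config),
    "kie"           = stage_kie(config),
    "collide"       = stage_collide(config),
    "fit-threshold" = stage_fit_threshold(config),
    "synth"         = stage_synth(config))

  for (nm in names(result$tables)) {
    utils::write.table(result$tables[[nm]],
                       file.path(config$output_dir, paste0(nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    log_lines <- c(log_lines, sprintf("stage %s: wrote %s.tsv", sub, nm))
  }
  cfg_sorted <- config[order(names(config))]
  summary <- list(
    package = "gibkin",
    version = as.character(utils::packageVersion("gibkin")),
    subcommand = sub,
    seed = config$seed %||% NA,
    config = cfg_sorted,
    config_hash = config_hash(cfg_sorted),
    outputs = paste0(names(result$tables), ".tsv"),
    results = result$summary
  )
  jsonlite::write_json(summary,
                       file.path(config$output_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null", na = "null")
  writeLines(c(log_lines, sprintf("stage %s: done", sub)), log_path)
  invisible(summary)
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(as.character(jsonlite::toJSON(config, auto_unbox = TRUE,
                                           digits = NA)), tmp)
  unname(tools::md5sum(tmp))
}

need_keys <- function(config, keys, sub) {
  miss <- keys[!keys %in% names(config)]
  if (length(miss))
    stop("configuration error in `", sub, "`: missing key(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
}

freqs_from <- function(x) {
  if (is.character(x) && length(x) == 1L) {
    if (!file.exists(x)) stop("missing input file: ", x, call. = FALSE)
    read_frequencies(x)
  } else as.numeric(x)
}

stage_thermo_cycle <- function(cfg) {
  need_keys(cfg, c("aip_neutral", "aip_parent", "acidities", "basicity"),
            "thermo-cycle")
  ct <- ct_endothermicity(cfg$aip_neutral, cfg$aip_parent)
  ac <- unlist(cfg$acidities)
  pt <- vapply(ac, pt_threshold, numeric(1), basicity = cfg$basicity)
  tab <- data.frame(
    quantity = c("CT_endothermicity", paste0("PT_threshold_", names(ac))),
    value_eV = c(ct, pt))
  list(tables = list(thermo_cycle = tab),
       summary = list(ct_ev = ct, pt_min_ev = min(pt), pt_max_ev = max(pt)))
}

stage_wigner <- function(cfg) {
  need_keys(cfg, "imag_freqs", "wigner")
  T <- cfg$temperature %||% 298
  f <- as.numeric(unlist(cfg$imag_freqs))
  tab <- data.frame(imag_freq_cm = f, temperature_K = T,
                    wigner_factor = wigner_factor(f, T))
  list(tables = list(wigner = tab), summary = list(temperature_K = T))
}

rrkm_table <- function(cfg, suffix = "") {
  pick <- function(key) cfg[[paste0(key, suffix)]]
  rc <- beyer_swinehart(freqs_from(pick("reactant_frequencies")),
                        grain = cfg$grain_cm %||% 10,
                        e_max = cfg$e_max_cm)
  ts <- beyer_swinehart(freqs_from(pick("ts_frequencies")),
                        grain = cfg$grain_cm %||% 10,
                        e_max = cfg$e_max_cm)
  e <- as.numeric(cfg$e_grid_ev)
  rrkm_k(e, pick("e0_ev"), rc, ts, symmetry = cfg$symmetry %||% 1,
         rho_width = cfg$rho_width %||% 100)
}

stage_rrkm <- function(cfg) {
  need_keys(cfg, c("reactant_frequencies", "ts_frequencies", "e0_ev",
                   "e_grid_ev", "e_max_cm"), "rrkm")
  e <- as.numeric(cfg$e_grid_ev)
  k <- rrkm_table(cfg)
  tab <- data.frame(E_eV = e, k_per_s = k)
  list(tables = list(rrkm = tab),
       summary = list(k_min_per_s = min(k), k_max_per_s = max(k)))
}

stage_kie <- function(cfg) {
  need_keys(cfg, c("reactant_frequencies_light", "ts_frequencies_light",
                   "e0_ev_light", "reactant_frequencies_heavy",
                   "ts_frequencies_heavy", "e0_ev_heavy", "e_grid_ev",
                   "e_max_cm"), "kie")
  e <- as.numeric(cfg$e_grid_ev)
  kl <- rrkm_table(cfg, "_light")
  kh <- rrkm_table(cfg, "_heavy")
  tab <- data.frame(E_eV = e, k_light_per_s = kl, k_heavy_per_s = kh,
                    kie = kie_ratio(kl, kh))
  list(tables = list(kie = tab),
       summary = list(kie_min = min(tab$kie, na.rm = TRUE),
                      kie_max = max(tab$kie, na.rm = TRUE)))
}

stage_collide <- function(cfg) {
  need_keys(cfg, c("polarizability_a3", "e_grid_ev"), "collide")
  e <- as.numeric(cfg$e_grid_ev)
  cap <- capture_sigma(cfg$polarizability_a3, cfg$dipole_d %||% 0,
                       cfg$charge %||% 1, cfg$temperature %||% 310, e)
  hs <- if (!is.null(cfg$xyz_ion) && !is.null(cfg$xyz_neutral)) {
    as.numeric(projected_area_sigma(
      read_xyz(cfg$xyz_ion), NULL, read_xyz(cfg$xyz_neutral), NULL,
      n_orientations = cfg$n_orientations %||% 500,
      seed = cfg$seed %||% 1))
  } else cfg$hard_sphere_a2 %||% 0
  tab <- data.frame(E_CM_eV = e, capture_A2 = cap,
                    hard_sphere_A2 = hs,
                    collision_A2 = collision_sigma(cap, hs))
  list(tables = list(collide = tab),
       summary = list(hard_sphere_a2 = unique(hs)[1]))
}

beam_from_config <- function(cfg) {
  need_keys(cfg, c("m_ion", "m_neutral"), cfg$subcommand)
  beam_conditions(
    m_ion = cfg$m_ion, m_neutral = cfg$m_neutral,
    t_ion = cfg$t_ion %||% 310, t_neutral = cfg$t_neutral %||% 310,
    fwhm_lab = cfg$fwhm_lab %||% 0.65,
    detection_window = cfg$detection_window %||% 1e-4,
    ion_frequencies = freqs_from(cfg$ion_frequencies %||% numeric()),
    neutral_frequencies = freqs_from(cfg$neutral_frequencies %||% numeric()),
    ion_rotor = cfg$ion_rotor %||% "nonlinear",
    neutral_rotor = cfg$neutral_rotor %||% "nonlinear")
}

stage_fit_threshold <- function(cfg) {
  need_keys(cfg, "data", "fit-threshold")
  if (!file.exists(cfg$data)) stop("missing input: ", cfg$data,
                                   call. = FALSE)
  curve <- read_curve(cfg$data)
  cond <- beam_from_config(cfg)
  fit <- fit_threshold(curve, cond,
                       n_range = c(cfg$n_min %||% 2.0, cfg$n_max %||% 3.0),
                       n_samples = cfg$n_samples %||% 300,
                       seed = cfg$seed)
  params <- data.frame(
    parameter = c("sigma0_A2_eV", "E0_eV", "n", "E0_unc_eV",
                  "E0_spread_n_eV", "E0_sd_ecm_eV"),
    value = c(fit$params$sigma0, fit$e0, fit$params$n, fit$e0_uncertainty,
              fit$e0_spread_n, fit$e0_sd_ecm))
  best <- data.frame(E_CM_eV = fit$best_fit$e_cm_ev,
                     sigma_A2 = fit$best_fit$sigma_a2,
                     sigma_err_A2 = fit$best_fit$sigma_err_a2)
  scan <- fit$scan
  names(scan) <- c("n", "E0_eV", "sigma0_A2_eV", "objective")
  list(tables = list(fit_params = params, best_fit_curve = best,
                     n_scan = scan),
       summary = list(e0_ev = fit$e0, e0_unc_ev = fit$e0_uncertainty,
                      n = fit$params$n))
}

stage_synth <- function(cfg) {
  need_keys(cfg, c("sigma0", "e0_ev", "n", "e_grid_ev"), "synth")
  cond <- beam_from_config(cfg)
  curve <- gen_curve(loc_params(cfg$sigma0, cfg$e0_ev, cfg$n), cond,
                     as.numeric(cfg$e_grid_ev),
                     noise_cv = cfg$noise_cv %||% 0.05,
                     n_samples = cfg$n_samples %||% 500, seed = cfg$seed)
  tab <- data.frame(E_CM_eV = curve$e_cm_ev, sigma_A2 = curve$sigma_a2,
                    sigma_err_A2 = curve$sigma_err_a2)
  list(tables = list(synthetic_curve = tab),
       summary = list(n_points = nrow(tab),
                      sigma_max_a2 = max(tab$sigma_A2)))
}
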
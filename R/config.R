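## Configuration documents and file-based workflow: everything needed to run
## the analysis end to end from a single JSON config, with CSV/JSON outputs
## and a reproducibility manifest.

surv_model_to_list <- function(model) {
  list(family = model$family, param_names = names(model$params),
       param_values = unname(model$params), knots = model$knots,
       scale_kind = model$scale_kind, powers = model$powers,
       cutpoints = model$cutpoints, loglik = model$loglik,
       n_obs = model$n_obs, convergence = model$convergence,
       diagnostic = model$diagnostic)
}

surv_model_from_list <- function(x) {
  surv_model(x$family, stats::setNames(unlist(x$param_values),
                                       unlist(x$param_names)),
             knots = unlist(x$knots), scale_kind = x$scale_kind,
             powers = unlist(x$powers), cutpoints = unlist(x$cutpoints),
             loglik = x$loglik %||% NA_real_,
             n_obs = x$n_obs %||% NA_integer_,
             convergence = x$convergence %||% TRUE,
             diagnostic = x$diagnostic)
}

#' Write and read the analysis configuration document
#'
#' A single JSON document carries the full analysis: the parameter table
#' (published row labels verbatim, with base/min/max/distribution), model
#' settings, both strategies with their survival models, the scenario list
#' and the probabilistic-analysis settings. The shipped default is
#' `system.file("extdata", "base_case_config.json", package = "psmcea")`.
#'
#' @param bc A list as returned by [base_case()].
#' @param path JSON file path.
#' @param scenarios List of scenario entries (`name` plus `horizon_years`
#'   and/or `multipliers`).
#' @param psa List with `n_iter` and `seed`.
#' @return `write_run_config` returns `path` invisibly; `load_run_config`
#'   the restored list (`inputs`, `strategies`, `ranges`, `scenarios`,
#'   `psa`).
#' @export
write_run_config <- function(bc, path,
                             scenarios = default_scenarios(),
                             psa = list(n_iter = 1000, seed = 1)) {
  tab <- table1_parameters()
  tab$base <- unname(bc$inputs$params[tab$name])
  params <- lapply(seq_len(nrow(tab)), function(i)
    list(name = tab$name[i], base = tab$base[i], min = tab$min[i],
         max = tab$max[i], distribution = tab$dist[i]))
  names(params) <- tab$label
  doc <- list(
    parameters = params,
    settings = bc$inputs$settings,
    strategies = lapply(bc$strategies, function(s)
      list(arm = s$arm, second_line_mix = as.list(s$second_line_mix),
           os_model = surv_model_to_list(s$os_model),
           pfs_model = surv_model_to_list(s$pfs_model))),
    scenarios = scenarios,
    psa = psa)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, na = "null",
                       null = "null", pretty = TRUE)
  invisible(path)
}

default_scenarios <- function() {
  list(list(name = "trial_followup_4.5y", horizon_years = 4.5),
       list(name = "atezolizumab_price_minus_10pct",
            multipliers = list(cost_atezolizumab = 0.9)))
}

#' @rdname write_run_config
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  doc <- jsonlite::read_json(path)
  tab <- do.call(rbind, lapply(names(doc$parameters), function(lbl) {
    p <- doc$parameters[[lbl]]
    data.frame(name = p$name, label = lbl, base = p$base,
               min = p$min, max = p$max, dist = p$distribution)
  }))
  st <- doc$settings
  inputs <- economic_inputs(
    params = stats::setNames(tab$base, tab$name),
    wtp = st$wtp, cycle_days = st$cycle_days,
    horizon_years = st$horizon_years,
    chemo_max_cycles = st$chemo_max_cycles,
    monitoring_interval = st$monitoring_interval,
    hospice_accrual = st$hospice_accrual,
    ae_disutility_cycles = st$ae_disutility_cycles,
    bsa_reference = st$bsa_reference %||% 1.95)
  strategies <- lapply(doc$strategies, function(s)
    strategy_config(s$arm, surv_model_from_list(s$os_model),
                    surv_model_from_list(s$pfs_model),
                    second_line_mix = unlist(s$second_line_mix)))
  ranges <- param_ranges(tab[tab$max > tab$min, ])
  list(inputs = inputs, strategies = strategies, ranges = ranges,
       scenarios = doc$scenarios, psa = doc$psa)
}

result_row <- function(label, res) {
  data.frame(
    scenario = label,
    arm = c(res$comparator$arm, res$intervention$arm),
    cost = c(res$comparator$cost, res$intervention$cost),
    qaly = c(res$comparator$qaly, res$intervention$qaly),
    delta_cost = c(NA, res$delta_cost),
    delta_qaly = c(NA, res$delta_qaly),
    icer = c(NA, res$icer))
}

write_manifest <- function(out_dir, config_path = NULL, seed = NULL) {
  manifest <- list(
    package = "psmcea",
    version = as.character(utils::packageVersion("psmcea")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config_md5 = if (!is.null(config_path))
      unname(tools::md5sum(config_path)) else NULL)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, null = "null", pretty = TRUE)
}

#' File-based workflow commands
#'
#' Thin file-in/file-out wrappers tying the stages together; these back the
#' command-line script in `inst/cli/psmcea.R`.
#'
#' `cea_run` executes the base case and every configured scenario, writing
#' `results.csv` (arm, cost, qaly, delta_cost, delta_qaly, icer), a
#' `report.json` with per-component cost breakdowns, and a reproducibility
#' manifest. `cea_owsa` writes the tornado table; `cea_psa` writes the
#' replicate-level samples and the acceptability curve; `cea_fit` fits the
#' candidate survival models to a digitized curve and writes the selection
#' table plus serialized fitted models; `cea_simulate` writes synthetic
#' digitized-curve fixtures.
#'
#' @param config_path Path to a [write_run_config()] document.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
cea_run <- function(config_path, out_dir) {
  cfg <- load_run_config(config_path)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- run_comparison(cfg$inputs, cfg$strategies$ABC, cfg$strategies$BC)
  rows <- result_row("base_case", res)
  report <- list(base_case = cea_result_report(res))
  for (sc in cfg$scenarios) {
    mod <- apply_scenario(cfg$inputs,
                          multipliers = unlist(sc$multipliers),
                          horizon_years = sc$horizon_years)
    r <- run_comparison(mod, cfg$strategies$ABC, cfg$strategies$BC)
    rows <- rbind(rows, result_row(sc$name, r))
    report[[sc$name]] <- cea_result_report(r)
  }
  paths <- file.path(out_dir, c("results.csv", "report.json"))
  utils::write.csv(rows, paths[1], row.names = FALSE)
  jsonlite::write_json(report, paths[2], auto_unbox = TRUE, digits = NA, na = "null",
                       null = "null", pretty = TRUE)
  write_manifest(out_dir, config_path)
  invisible(paths)
}

cea_result_report <- function(res) {
  list(intervention = list(arm = res$intervention$arm,
                           cost = res$intervention$cost,
                           qaly = res$intervention$qaly,
                           components = as.list(res$intervention$components)),
       comparator = list(arm = res$comparator$arm,
                         cost = res$comparator$cost,
                         qaly = res$comparator$qaly,
                         components = as.list(res$comparator$components)),
       delta_cost = res$delta_cost, delta_qaly = res$delta_qaly,
       icer = res$icer, dominance = res$dominance, nmb = res$nmb)
}

#' @rdname cea_run
#' @export
cea_owsa <- function(config_path, out_dir) {
  cfg <- load_run_config(config_path)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  to <- owsa_tornado(cfg$inputs, cfg$strategies$ABC, cfg$strategies$BC,
                     cfg$ranges)
  path <- file.path(out_dir, "tornado.csv")
  utils::write.csv(as.data.frame(to), path, row.names = FALSE)
  write_manifest(out_dir, config_path)
  invisible(path)
}

#' @rdname cea_run
#' @param seed Overrides the configured PSA seed.
#' @export
cea_psa <- function(config_path, out_dir, seed = NULL) {
  cfg <- load_run_config(config_path)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- seed %||% cfg$psa$seed %||% 1
  psa <- run_psa(cfg$inputs, cfg$strategies$ABC, cfg$strategies$BC,
                 cfg$ranges, n_iter = cfg$psa$n_iter %||% 1000, seed = seed)
  paths <- file.path(out_dir, c("psa_samples.csv", "ceac.csv",
                                "psa_summary.json"))
  utils::write.csv(psa$samples, paths[1], row.names = FALSE)
  utils::write.csv(ceac_curve(psa), paths[2], row.names = FALSE)
  jsonlite::write_json(list(n_iter = psa$n_iter, wtp = psa$wtp, seed = seed,
                            prob_cost_effective = psa$prob_ce),
                       paths[3], auto_unbox = TRUE, digits = NA)
  write_manifest(out_dir, config_path, seed = seed)
  invisible(paths)
}

#' @rdname cea_run
#' @param curve_file,risk_file Digitized-curve CSV pair (see
#'   [read_digitized_curve()]).
#' @param arm,endpoint Labels for the curve.
#' @param criterion Selection criterion.
#' @export
cea_fit <- function(curve_file, risk_file, out_dir, arm = "arm",
                    endpoint = "endpoint", criterion = "AIC") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  curve <- read_digitized_curve(curve_file, risk_file, arm, endpoint)
  ipd <- reconstruct_ipd(curve)
  fits <- fit_candidate_set(ipd)
  report <- select_best_model(fits, criterion)
  sel_path <- file.path(out_dir, sprintf("selection_%s_%s.csv", arm, endpoint))
  utils::write.csv(as.data.frame(report)[order(report$rank), ],
                   sel_path, row.names = FALSE)
  model_paths <- vapply(names(fits), function(nm) {
    pth <- file.path(out_dir, sprintf("model_%s_%s_%s.json", arm, endpoint, nm))
    write_surv_model(fits[[nm]], pth)
    pth
  }, character(1))
  write_manifest(out_dir)
  invisible(c(sel_path, model_paths))
}

#' @rdname cea_run
#' @param n Per-arm sample size of the simulated trial.
#' @export
cea_simulate <- function(out_dir, n = 206, seed = 1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_reference_trial(n = n, seed = seed)
  paths <- character(0)
  for (arm in names(sim)) for (ep in names(sim[[arm]])) {
    curve <- generate_km_fixture(sim[[arm]][[ep]], seed = seed)
    pc <- file.path(out_dir, sprintf("curve_%s_%s.csv", arm, toupper(ep)))
    pr <- file.path(out_dir, sprintf("risk_%s_%s.csv", arm, toupper(ep)))
    write_digitized_curve(curve, pc, pr)
    paths <- c(paths, pc, pr)
  }
  write_manifest(out_dir, seed = seed)
  invisible(paths)
}
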
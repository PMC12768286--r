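PARAM_KEYS <- c("r", "kappa", "a", "sigma", "gamma", "dS", "dL", "dSstar",
                "dLstar", "B", "dV", "piV", "piL", "dA", "delta", "k")
FORCING_KEYS <- c("mode", "theta0", "thetaMax", "g", "T")
STRATEGY_KEYS <- c("kind", "phi", "phiStar", "alpha", "alphaStar",
                   "alphaMax", "phiMax", "alphaMaxStar", "phiMaxStar",
                   "Aalpha", "Aphi", "AalphaStar", "AphiStar")

#' Read a model configuration file
#'
#' Parses a YAML (or JSON, which YAML subsumes) configuration with the
#' optional sections `params`, `forcing`, `strategy` and `scenario`.
#' Missing keys fall back to the package defaults; unknown keys are a hard
#' error; out-of-range values are rejected naming the offending key.
#'
#' @param path Path to the configuration file.
#' @return A list with elements `params` (`phage_params`), `forcing`
#'   (`phage_forcing`), `strategy` (`phage_strategy`) and `scenario`
#'   (scenario name or `NULL`).
#' @seealso [write_config()]
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  bad <- setdiff(names(cfg), c("params", "forcing", "strategy", "scenario"))
  if (length(bad))
    stop("unknown configuration section(s): ", paste(bad, collapse = ", "),
         call. = FALSE)

  pl <- cfg$params %||% list()
  chk_keys(pl, PARAM_KEYS, "params")
  params <- do.call(model_params, pl)

  fl <- cfg$forcing %||% list()
  chk_keys(fl, FORCING_KEYS, "forcing")
  mode <- fl$mode %||% "square_wave"
  fl$mode <- NULL
  forcing <- if (identical(mode, "constant")) {
    do.call(forcing_constant, fl)
  } else if (identical(mode, "square_wave")) {
    do.call(forcing_square, fl)
  } else stop("forcing 'mode' must be 'constant' or 'square_wave'",
              call. = FALSE)

  sl <- cfg$strategy %||% list()
  chk_keys(sl, STRATEGY_KEYS, "strategy")
  kind <- sl$kind %||% "fixed"
  sl$kind <- NULL
  strategy <- if (identical(kind, "fixed")) {
    do.call(strategy_fixed, sl)
  } else if (identical(kind, "plastic")) {
    do.call(strategy_plastic, sl)
  } else stop("strategy 'kind' must be 'fixed' or 'plastic'",
              call. = FALSE)

  scen <- cfg$scenario
  if (!is.null(scen) && !scen %in% SCENARIO_NAMES)
    stop("unknown scenario name: ", scen, call. = FALSE)
  list(params = params, forcing = forcing, strategy = strategy,
       scenario = scen)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

chk_keys <- function(x, allowed, section) {
  bad <- setdiff(names(x), allowed)
  if (length(bad))
    stop("unknown key(s) in '", section, "': ",
         paste(bad, collapse = ", "), call. = FALSE)
}

#' Write a model configuration file
#'
#' Serialises parameters, forcing and strategy (and optionally a scenario
#' name) to YAML such that [load_config()] reproduces them exactly.
#'
#' @param params A `phage_params` object.
#' @param forcing A `phage_forcing` object.
#' @param strategy A `phage_strategy` object.
#' @param path Output file path.
#' @param scenario Optional scenario name.
#' @return Invisibly, `path`.
#' @export
write_config <- function(params, forcing, strategy, path,
                         scenario = NULL) {
  stopifnot(inherits(params, "phage_params"),
            inherits(forcing, "phage_forcing"),
            inherits(strategy, "phage_strategy"))
  strat <- Filter(function(x) !(is.numeric(x) && is.na(x)),
                  unclass(strategy))
  cfg <- list(params = unclass(params), forcing = unclass(forcing),
              strategy = strat)
  if (!is.null(scenario)) cfg$scenario <- scenario
  yaml::write_yaml(cfg, path, precision = 15L)
  invisible(path)
}

#' Export attractor, arbitrium, selection-sign and reaction-norm panels
#'
#' Writes four headered CSV files summarising one consistent scenario:
#' `panelA_densities.csv` (cell and virion densities against time over one
#' period), `panelB_arbitrium.csv` (arbitrium concentration),
#' `panelC_selection.csv` (the selection-sign series `B vV - vL` and
#' `B vV - vLstar`), and `panelD_norms.csv` (the reaction norms
#' `alpha(A)`, `phi(A)`, `alphaStar(A)`, `phiStar(A)` sampled over the
#' attractor's arbitrium range).
#'
#' @param att A `phage_attractor`.
#' @param profile The matching `selection_profile`.
#' @param strategy Strategy whose norms fill panel D; defaults to the
#'   attractor's resident strategy.
#' @param outdir Output directory (created if missing).
#' @return Invisibly, the vector of file paths.
#' @export
export_figure_panels <- function(att, profile, strategy = NULL,
                                 outdir = ".") {
  stopifnot(inherits(att, "phage_attractor"),
            inherits(profile, "selection_profile"))
  if (!isTRUE(all.equal(att$times, profile$series$time)))
    stop("attractor and profile are on different time grids", call. = FALSE)
  if (is.null(strategy)) strategy <- att$strategy
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  fp <- file.path(outdir, c("panelA_densities.csv", "panelB_arbitrium.csv",
                            "panelC_selection.csv", "panelD_norms.csv"))
  st <- att$states
  utils::write.csv(data.frame(t = att$times, st[, c("S", "Sstar", "L",
                                                    "Lstar", "V")],
                              theta = influx(att$times %% att$period,
                                             att$forcing)),
                   fp[1], row.names = FALSE)
  utils::write.csv(data.frame(t = att$times, A = st[, "A"]),
                   fp[2], row.names = FALSE)
  s <- profile$series
  B <- att$params$B
  utils::write.csv(data.frame(t = s$time,
                              lysis_signal_normal = B * s$vV - s$vL,
                              lysis_signal_stressed = B * s$vV - s$vLstar),
                   fp[3], row.names = FALSE)
  A_grid <- seq(0, max(st[, "A"]) * 1.2, length.out = 201L)
  tr <- evaluate_strategy(strategy, A_grid, k = att$params$k)
  utils::write.csv(data.frame(A = A_grid, alpha = tr$alpha, phi = tr$phi,
                              alphaStar = tr$alphaStar,
                              phiStar = tr$phiStar),
                   fp[4], row.names = FALSE)
  invisible(fp)
}

#' Deterministic run manifest
#'
#' Records everything needed to reproduce a run: an MD5 hash of the
#' configuration file, the resolved parameter set, the scenario, solver
#' tolerances, the package version and the multi-start seed. Identical
#' manifests imply identical CSV/JSON outputs up to the platform's
#' floating-point determinism.
#'
#' @param config_path Path to the configuration file used.
#' @param scenario Scenario name (or `NULL`).
#' @param tolerances Named list of solver/integration tolerances.
#' @param seed Multi-start seed (or `NULL`).
#' @param path Optional output path; when given the manifest is written
#'   as JSON.
#' @return The manifest as a list, invisibly when written.
#' @export
run_manifest <- function(config_path, scenario = NULL,
                         tolerances = list(rtol = 1e-8, atol = 1e-10,
                                           attractor_tol = 1e-6,
                                           gtol = 1e-7),
                         seed = NULL, path = NULL) {
  cfg <- load_config(config_path)
  man <- list(
    config_md5 = unname(tools::md5sum(config_path)),
    params = unclass(cfg$params),
    forcing = unclass(cfg$forcing),
    strategy = unclass(cfg$strategy),
    scenario = scenario %||% cfg$scenario,
    tolerances = tolerances,
    seed = seed,
    package_version = as.character(utils::packageVersion("lysogeny"))
  )
  if (!is.null(path)) {
    jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
    return(invisible(man))
  }
  man
}
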
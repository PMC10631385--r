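#' Run the full modelling pipeline from a configuration
#'
#' Drives ingest -> smooth -> fit -> forecast (-> evaluate) from a flat
#' configuration and writes CSV artifacts plus a run log to an output
#' directory.  Identical configuration and seed give identical outputs.
#' This is the engine behind the command-line interface
#' (`inst/cli/wmfpca-cli.R`); interactive users normally call the
#' underlying functions directly.
#'
#' Recognised keys (defaults in parentheses): `input` (character vector of
#' surface CSV paths, read with [read_csv_surface()]) or `simulate`
#' (`TRUE` to use the synthetic generator), `hmd` + `sex` + `max_age` (100)
#' to ingest an HMD file instead, `model` ("coherent"), `kappa` (0, or
#' `"tune"`), `kappa_grid`, `P` (0.9), `pivot_age` (65), `h` (20),
#' `alpha` (0.05), `seed` (1), `n_pop` (2), `n_years` (60), `age_max`
#' (100), `n_windows` (4), `evaluate` (FALSE), `out` (required).
#'
#' @param config named list, or path to a `key=value` text file.
#' @return Invisibly, a list with the fitted model, the forecast and the
#'   paths written.
#' @export
run_pipeline <- function(config) {
  cfg <- normalise_config(config)
  dir.create(cfg$out, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed)

  data <- if (!is.null(cfg$hmd)) {
    read_hmd_mx(cfg$hmd, population = paste0("hmd_", cfg$sex), sex = cfg$sex,
                max_age = cfg$max_age)
  } else if (!is.null(cfg$input)) {
    dplyr::bind_rows(lapply(cfg$input, function(f) {
      read_csv_surface(f, population = sub("\\.csv$", "", basename(f)))
    }))
  } else if (isTRUE(cfg$simulate)) {
    sim <- generate_mortality(synthetic_spec(
      n_pop = cfg$n_pop, n_years = cfg$n_years, ages = 0:cfg$age_max,
      seed = cfg$seed))
    sim$data
  } else {
    abort("config must provide 'input', 'hmd' or 'simulate=TRUE'")
  }

  log_lines <- c(
    paste0("wmfpca ", as.character(utils::packageVersion("wmfpca"))),
    paste0("R ", R.version.string),
    paste0("seed ", cfg$seed),
    paste0("model ", cfg$model),
    paste0("populations ", paste(unique(data$population), collapse = ","))
  )

  curves <- smooth_surface(data, pivot_age = cfg$pivot_age)

  kappa <- cfg$kappa
  if (identical(kappa, "tune")) {
    tuned <- tune_kappa(data, model = cfg$model, h = min(cfg$h, 5L),
                        grid = cfg$kappa_grid, n_windows = cfg$n_windows,
                        pivot_age = cfg$pivot_age)
    kappa <- tuned$kappa
    readr::write_csv(tuned$profile, file.path(cfg$out, "kappa_profile.csv"))
    log_lines <- c(log_lines, paste0("tuned kappa ", kappa))
  }
  kappa <- as.numeric(kappa)

  fit <- switch(cfg$model,
    coherent    = fit_coherent(curves, kappa = kappa, P = cfg$P),
    wmfpca      = fit_wmfpca(curves, kappa = kappa, P = cfg$P),
    independent = fit_independent(curves, kappa = kappa, P = cfg$P)
  )
  fc <- forecast(fit, h = cfg$h, alpha = cfg$alpha)

  paths <- c(
    forecasts = file.path(cfg$out, "forecasts.csv"),
    components = file.path(cfg$out, "components.csv"),
    scores = file.path(cfg$out, "scores.csv"),
    log = file.path(cfg$out, "run_log.txt")
  )
  readr::write_csv(tidy(fc), paths[["forecasts"]])
  readr::write_csv(tidy(fit), paths[["components"]])
  readr::write_csv(score_series(fit), paths[["scores"]])

  if (isTRUE(cfg$evaluate)) {
    ev <- rolling_rmse(data, model = cfg$model, h = min(cfg$h, 5L),
                       n_windows = cfg$n_windows, kappa = kappa, P = cfg$P,
                       pivot_age = cfg$pivot_age)
    paths[["evaluation"]] <- file.path(cfg$out, "evaluation.csv")
    readr::write_csv(ev$by_population, paths[["evaluation"]])
  }

  writeLines(log_lines, paths[["log"]])
  invisible(list(fit = fit, forecast = fc, paths = paths))
}

pipeline_defaults <- function() {
  list(
    input = NULL, hmd = NULL, sex = "total", max_age = 100, simulate = FALSE,
    model = "coherent", kappa = 0, kappa_grid = c(0, 0.05, 0.1, 0.2),
    P = 0.9, pivot_age = 65, h = 20L, alpha = 0.05, seed = 1L,
    n_pop = 2L, n_years = 60L, age_max = 100L, n_windows = 4L,
    evaluate = FALSE, out = NULL
  )
}

normalise_config <- function(config) {
  if (is.character(config) && length(config) == 1L && file.exists(config)) {
    lines <- grep("^\\s*(#|$)", readLines(config), value = TRUE, invert = TRUE)
    kv <- strsplit(lines, "=", fixed = TRUE)
    config <- setNames(
      lapply(kv, function(x) utils::type.convert(trimws(paste(x[-1], collapse = "=")),
                                                 as.is = TRUE)),
      vapply(kv, function(x) trimws(x[1]), "")
    )
  }
  if (!is.list(config)) abort("config must be a named list or a key=value file path")
  defaults <- pipeline_defaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) {
    abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  cfg <- utils::modifyList(defaults, config)
  if (is.null(cfg$out)) abort("config key 'out' (output directory) is required")
  if (!cfg$model %in% c("coherent", "wmfpca", "independent")) {
    abort("model must be one of coherent, wmfpca, independent")
  }
  if (!identical(cfg$kappa, "tune")) {
    k <- suppressWarnings(as.numeric(cfg$kappa))
    if (is.na(k) || k < 0 || k >= 1) abort("kappa must be in [0, 1) or \"tune\"")
    cfg$kappa <- k
  }
  if (cfg$alpha <= 0 || cfg$alpha >= 1) abort("alpha must be in (0, 1)")
  if (cfg$h < 1) abort("h must be at least 1")
  cfg$seed <- as.integer(cfg$seed)
  cfg$h <- as.integer(cfg$h)
  cfg
}
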
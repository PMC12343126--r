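#' Specification of a dose-by-fecundity equilibrium sweep
#'
#' @param vary which brood-size parameter to vary: `"b_SRSR"`,
#'   `"b_SRST"` or `"b_STST"`.
#' @param dose_grid strictly increasing dose grid in ml; the default 26
#'   points over 0-2.5 ml deliberately extends beyond the empirical
#'   1.8 ml range, because the all-genotype lethal point sits outside
#'   it on the logit-linear extrapolation.
#' @param fecundity_grid strictly increasing brood-size values; default
#'   (`NULL`) resolves at run time to 5 points spanning the varied
#'   genotype's median +/- half-width band.
#' @return object of class `sweep_spec`.
#' @export
sweep_spec <- function(vary = c("b_SRSR", "b_SRST", "b_STST"),
                       dose_grid = seq(0, 2.5, length.out = 26),
                       fecundity_grid = NULL) {
  vary <- match.arg(vary)
  if (length(dose_grid) == 0L || any(diff(dose_grid) <= 0)) {
    stop("'dose_grid' must be non-empty and strictly increasing")
  }
  if (!is.null(fecundity_grid)) {
    if (length(fecundity_grid) == 0L || any(diff(fecundity_grid) <= 0)) {
      stop("'fecundity_grid' must be non-empty and strictly increasing")
    }
    if (any(fecundity_grid < 0)) stop("fecundity values must be >= 0")
  }
  structure(list(vary = vary, dose_grid = dose_grid,
                 fecundity_grid = fecundity_grid),
            class = "sweep_spec")
}

.vary_genotype <- function(vary) sub("^b_", "", vary)

.resolve_fec_grid <- function(spec, params, n = 5L) {
  if (!is.null(spec$fecundity_grid)) return(spec$fecundity_grid)
  g <- .vary_genotype(spec$vary)
  lo <- params$fecundity$ranges["lo", g]
  hi <- params$fecundity$ranges["hi", g]
  seq(lo, hi, length.out = n)
}

#' Run a dose-by-fecundity equilibrium sweep
#'
#' Every grid cell substitutes the varied brood size into the model
#' parameters and simulates to `t_max`; the SR-male and SRSR-female
#' frequencies at the final generation are recorded. Extinct cells get
#' `NA` frequencies (undefined by flag). Fully deterministic.
#'
#' @param spec a [sweep_spec()].
#' @param params a [model_params()] object.
#' @return data.frame of class `sweep_result`, one row per grid cell:
#'   `dose_ml, varied_param, varied_value, sr_male_freq,
#'   srsr_female_freq, extinct, t_final`.
#' @export
run_sweep <- function(spec, params) {
  stopifnot(inherits(spec, "sweep_spec"), inherits(params, "model_params"))
  fec_grid <- .resolve_fec_grid(spec, params)
  if (any(fec_grid < 0)) stop("fecundity values must be >= 0")
  g <- .vary_genotype(spec$vary)
  rows <- vector("list", length(fec_grid) * length(spec$dose_grid))
  k <- 0L
  for (v in fec_grid) {
    p <- params
    b <- p$fecundity$b
    b[g] <- v
    p$fecundity <- fecundity_params(b, half_width = p$fecundity$half_width)
    for (dose in spec$dose_grid) {
      tr <- simulate_drive(p, dose)
      ext <- attr(tr, "extinct")
      last <- tr[nrow(tr), ]
      k <- k + 1L
      rows[[k]] <- data.frame(
        dose_ml = dose, varied_param = spec$vary, varied_value = v,
        sr_male_freq = if (ext) NA_real_ else last$sr_male_freq,
        srsr_female_freq = if (ext) NA_real_ else last$srsr_female_freq,
        extinct = ext, t_final = attr(tr, "t_final"),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("sweep_result", "data.frame")
  out
}

#' Smallest dose driving the population extinct
#'
#' Scans an increasing dose grid for the first dose whose simulation
#' ends extinct, then bisects between the bracketing grid points down
#' to `tol`. The threshold is a property of the parametrization, not of
#' the initial SR frequency.
#'
#' @param params a [model_params()] object.
#' @param dose_grid increasing dose grid to scan.
#' @param tol bisection tolerance in ml.
#' @return object of class `extinction_threshold`: list with `status`
#'   (`"ok"` or `"no threshold in range"`), `threshold` (refined dose,
#'   `NA` if none), `grid_dose` (first extinct grid dose) and `bracket`.
#' @export
find_extinction_threshold <- function(params,
                                      dose_grid = seq(0, 2.5,
                                                      length.out = 26),
                                      tol = 0.005) {
  stopifnot(inherits(params, "model_params"))
  if (any(diff(dose_grid) <= 0)) stop("'dose_grid' must be increasing")
  ext <- vapply(dose_grid,
                function(d) attr(simulate_drive(params, d), "extinct"),
                logical(1))
  if (!any(ext)) {
    return(structure(list(status = "no threshold in range",
                          threshold = NA_real_, grid_dose = NA_real_,
                          bracket = NULL),
                     class = "extinction_threshold"))
  }
  i <- which(ext)[1L]
  grid_dose <- dose_grid[i]
  if (i == 1L) {
    return(structure(list(status = "ok", threshold = grid_dose,
                          grid_dose = grid_dose,
                          bracket = c(NA_real_, grid_dose)),
                     class = "extinction_threshold"))
  }
  lo <- dose_grid[i - 1L]
  hi <- grid_dose
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (attr(simulate_drive(params, mid), "extinct")) hi <- mid else lo <- mid
  }
  structure(list(status = "ok", threshold = hi, grid_dose = grid_dose,
                 bracket = c(lo, hi)),
            class = "extinction_threshold")
}

#' @export
print.extinction_threshold <- function(x, ...) {
  if (x$status == "ok") {
    cat(sprintf("extinction threshold: %.4f ml (first extinct grid dose %.4f)\n",
                x$threshold, x$grid_dose))
  } else {
    cat("no extinction threshold in the scanned dose range\n")
  }
  invisible(x)
}

#' Shape diagnostics of a dose-frequency curve
#'
#' Purely descriptive summary of the equilibrium frequency series at
#' one fecundity value: the location of any strict interior extremum,
#' the mean second difference over interior points (positive = locally
#' convex / interior dip, negative = locally concave / interior bump),
#' and the largest deviations above and below the chord joining the
#' endpoints. Both readings of "concave" are reported rather than
#' asserted.
#'
#' @param result a [run_sweep()] result.
#' @param fecundity_value the `varied_value` selecting the series.
#' @param metric `"sr_male"` or `"srsr_female"`.
#' @return object of class `shape_diagnostic`: list with `dose`, `freq`,
#'   `mean_second_difference`, `interior_min_dose` / `interior_max_dose`
#'   (`NA` if the extremum is at an endpoint), `min_below_endpoints`,
#'   `max_above_endpoints`, `max_dev_below_chord`, `max_dev_above_chord`.
#' @export
shape_diagnostic <- function(result, fecundity_value,
                             metric = c("sr_male", "srsr_female")) {
  metric <- match.arg(metric)
  stopifnot(inherits(result, "sweep_result"))
  sel <- abs(result$varied_value - fecundity_value) < 1e-9 &
    !result$extinct
  d <- result[sel, , drop = FALSE]
  d <- d[order(d$dose_ml), , drop = FALSE]
  if (nrow(d) < 3L) stop("need >= 3 non-extinct doses for a shape diagnostic")
  f <- if (metric == "sr_male") d$sr_male_freq else d$srsr_female_freq
  x <- d$dose_ml
  n <- length(f)
  d2 <- f[seq(1L, n - 2L)] - 2 * f[seq(2L, n - 1L)] + f[seq(3L, n)]
  imin <- which.min(f)
  imax <- which.max(f)
  chord <- f[1L] + (f[n] - f[1L]) * (x - x[1L]) / (x[n] - x[1L])
  dev <- f - chord
  structure(list(
    dose = x, freq = f, metric = metric,
    mean_second_difference = mean(d2),
    interior_min_dose = if (imin > 1L && imin < n) x[imin] else NA_real_,
    interior_max_dose = if (imax > 1L && imax < n) x[imax] else NA_real_,
    min_below_endpoints = f[imin] < min(f[1L], f[n]),
    max_above_endpoints = f[imax] > max(f[1L], f[n]),
    max_dev_below_chord = -min(dev),
    max_dev_above_chord = max(dev)),
    class = "shape_diagnostic")
}

#' @export
print.shape_diagnostic <- function(x, ...) {
  cat(sprintf(
    "shape of %s frequency over %d doses: mean 2nd diff %.4g;\n",
    x$metric, length(x$dose), x$mean_second_difference))
  cat(sprintf("  interior min at %s, interior max at %s\n",
              format(x$interior_min_dose), format(x$interior_max_dose)))
  cat(sprintf("  max deviation below/above endpoint chord: %.4g / %.4g\n",
              x$max_dev_below_chord, x$max_dev_above_chord))
  invisible(x)
}

.content_hash <- function(txt) {
  # small polynomial content hash for run logs (no digest dependency)
  h <- 0
  for (b in utf8ToInt(txt)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

.stage <- function(name, log, code) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(code, error = function(e) {
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
  log$timings[[name]] <- proc.time()[["elapsed"]] - t0
  res
}

#' Run the full pipeline: data, fits, parametrization, sweeps
#'
#' Orchestrates generate (or read) -> fit -> build model parameters ->
#' equilibrium sweeps, writing every artifact to `config$output_dir`:
#' `mortality.csv`, `fecundity.csv`, `params.json`, one
#' `sweep_<param>.csv` per varied brood size, and `run_log.txt`
#' (seed, package version, resolved-config hash, per-stage timings).
#' With a fixed seed every data artifact is byte-identical across
#' re-runs; the run log differs only in its wall-clock timings.
#'
#' @param config configuration list, validated via [validate_config()].
#' @return (invisibly) list with the fitted objects, model params,
#'   sweep results and artifact paths.
#' @export
run_pipeline <- function(config = default_config()) {
  config <- validate_config(config)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  log <- new.env()
  log$timings <- list()

  mort <- .stage("generate_mortality", log, {
    if (!is.null(config$data$mortality_csv)) {
      read_vial_csv(config$data$mortality_csv)
    } else {
      generate_mortality_dataset(
        params = do.call(true_mortality_params, config$true_mortality),
        n_vials_per_genotype = config$design$n_vials_per_genotype,
        flies_per_vial_range = config$design$flies_per_vial,
        dose_values = seq(config$true_mortality$dose_range[1],
                          config$true_mortality$dose_range[2],
                          length.out = config$design$n_dose_levels),
        seed = config$seed + 1L)
    }
  })
  fec <- .stage("generate_fecundity", log, {
    if (!is.null(config$data$fecundity_csv)) {
      read_fecundity_csv(config$data$fecundity_csv)
    } else {
      generate_fecundity_dataset(
        params = do.call(true_fecundity_params, config$true_fecundity),
        n_females_per_genotype = config$design$n_females_per_genotype,
        dose_values = seq(config$true_mortality$dose_range[1],
                          config$true_mortality$dose_range[2],
                          length.out = config$design$n_dose_levels),
        seed = config$seed + 2L)
    }
  })
  fits <- .stage("fit", log, {
    mfit <- fit_mortality_glm(mort)
    ffit <- fit_fecundity_mixed(fec)
    list(mortality = mfit, fecundity = ffit)
  })
  params <- .stage("parametrize", log, {
    curves <- build_dose_response(fits$mortality)
    bpar <- build_fecundity_params(fec,
                                   half_width = config$sweep$fecundity_half_width)
    init <- do.call(init_state, config$model$init)
    model_params(curves, bpar, theta = config$model$theta, init = init,
                 t_max = config$model$t_max,
                 epsilon = config$model$epsilon_frac * sum(init$n),
                 efficacy = config$model$efficacy)
  })
  dose_grid <- seq(config$sweep$dose_grid$min, config$sweep$dose_grid$max,
                   length.out = config$sweep$dose_grid$n)
  sweeps <- .stage("sweep", log, {
    out <- lapply(config$sweep$vary, function(v) {
      spec <- sweep_spec(vary = v, dose_grid = dose_grid,
                         fecundity_grid = NULL)
      spec$fecundity_grid <- .resolve_fec_grid(spec, params,
                                               n = config$sweep$fecundity_n)
      run_sweep(spec, params)
    })
    names(out) <- config$sweep$vary
    out
  })
  paths <- .stage("write", log, {
    p <- list(
      mortality = file.path(config$output_dir, "mortality.csv"),
      fecundity = file.path(config$output_dir, "fecundity.csv"),
      params = file.path(config$output_dir, "params.json"),
      run_log = file.path(config$output_dir, "run_log.txt"))
    write_vial_csv(mort, p$mortality)
    write_fecundity_csv(fec, p$fecundity)
    write_params_file(params, p$params)
    for (v in names(sweeps)) {
      p[[paste0("sweep_", v)]] <-
        file.path(config$output_dir, paste0("sweep_", v, ".csv"))
      df <- sweeps[[v]]
      class(df) <- "data.frame"
      write.csv(df, p[[paste0("sweep_", v)]], row.names = FALSE,
                quote = FALSE)
    }
    p
  })
  cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                               null = "null")
  writeLines(c(
    sprintf("srdrive %s pipeline run", as.character(packageVersion("srdrive"))),
    sprintf("seed: %d", config$seed),
    sprintf("config_hash: %s", .content_hash(as.character(cfg_json))),
    sprintf("singular_fecundity_fit: %s", fits$fecundity$singular),
    sprintf("theta: %.10g", params$theta),
    "stage timings (s):",
    sprintf("  %s: %.3f", names(log$timings), unlist(log$timings)),
    "resolved config:",
    as.character(cfg_json)),
    con = paths$run_log)
  invisible(list(mortality_data = mort, fecundity_data = fec,
                 fits = fits, params = params, sweeps = sweeps,
                 paths = paths, config = config))
}
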
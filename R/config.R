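#' Default pipeline configuration
#'
#' A fully resolved configuration for [run_pipeline()]: the calibrated
#' synthetic world (generator truths), the experiment design sizes, the
#' model block and the sweep block. Any subset of these keys may be
#' overridden; [validate_config()] merges overrides onto these defaults
#' and rejects unknown keys.
#'
#' @return nested named list.
#' @export
default_config <- function() {
  tm <- true_mortality_params()
  tf <- true_fecundity_params()
  list(
    profile = "production",
    seed = 1234L,
    output_dir = "srdrive-run",
    data = list(mortality_csv = NULL, fecundity_csv = NULL),
    true_mortality = list(intercepts = tm$intercepts, slopes = tm$slopes,
                          dose_range = tm$dose_range),
    true_fecundity = list(log_means = tf$log_means,
                          dose_effect = tf$dose_effect,
                          sigma_vial = tf$sigma_vial,
                          sigma_id = tf$sigma_id),
    design = list(n_vials_per_genotype = 35L, flies_per_vial = c(7L, 11L),
                  n_females_per_genotype = 200L, n_dose_levels = 10L),
    model = list(theta = NULL, t_max = 1000L, epsilon_frac = 1e-6,
                 efficacy = 1,
                 init = list(n_total = 1000, sr_male_freq = 0.1,
                             srsr_freq = 0.01, srst_freq = 0.18)),
    sweep = list(dose_grid = list(min = 0, max = 2.5, n = 26L),
                 fecundity_half_width = 10, fecundity_n = 5L,
                 vary = c("b_SRSR", "b_SRST", "b_STST")))
}

.unknown_keys <- function(x, ref, prefix = "") {
  out <- character(0)
  extra <- setdiff(names(x), names(ref))
  if (length(extra) > 0L) {
    out <- paste0(prefix, extra)
  }
  for (k in intersect(names(x), names(ref))) {
    if (is.list(ref[[k]]) && !is.null(names(ref[[k]])) && is.list(x[[k]])) {
      out <- c(out, .unknown_keys(x[[k]], ref[[k]],
                                  prefix = paste0(prefix, k, "$")))
    }
  }
  out
}

#' Validate and resolve a pipeline configuration
#'
#' Merges the supplied (possibly partial) configuration onto
#' [default_config()], rejects unknown keys, and checks every
#' constraint, reporting all violations at once: integer seed,
#' resolvable data paths, `theta > 0` when given, `epsilon_frac > 0`,
#' positive design sizes, sane grids, and drive efficacy locked to 1
#' in the `production` profile (test profiles may override).
#'
#' @param config named list of overrides (possibly nested, possibly
#'   empty).
#' @return the fully resolved configuration.
#' @export
validate_config <- function(config = list()) {
  ref <- default_config()
  errors <- .unknown_keys(config, ref)
  if (length(errors) > 0L) {
    errors <- paste("unknown config key:", errors)
  }
  cfg <- modifyList(ref, config, keep.null = TRUE)
  chk <- function(ok, msg) if (!isTRUE(ok)) errors <<- c(errors, msg)
  chk(is.numeric(cfg$seed) && length(cfg$seed) == 1L &&
        cfg$seed == as.integer(cfg$seed),
      "seed must be a single integer")
  cfg$seed <- as.integer(cfg$seed)
  chk(cfg$profile %in% c("production", "test"),
      "profile must be 'production' or 'test'")
  for (k in c("mortality_csv", "fecundity_csv")) {
    p <- cfg$data[[k]]
    chk(is.null(p) || file.exists(p),
        sprintf("data$%s path not resolvable: %s", k, p))
  }
  chk(is.null(cfg$model$theta) || cfg$model$theta > 0,
      "model$theta must be > 0 (density dependence invariant)")
  chk(cfg$model$epsilon_frac > 0, "model$epsilon_frac must be > 0")
  chk(cfg$model$t_max >= 1, "model$t_max must be >= 1")
  if (cfg$profile == "production") {
    chk(identical(as.numeric(cfg$model$efficacy), 1),
        "drive efficacy must be 1 in the production profile")
  } else {
    chk(cfg$model$efficacy >= 0 && cfg$model$efficacy <= 1,
        "model$efficacy must be in [0, 1]")
  }
  chk(cfg$design$n_vials_per_genotype >= 1,
      "design$n_vials_per_genotype must be >= 1")
  chk(cfg$design$n_females_per_genotype >= 0,
      "design$n_females_per_genotype must be >= 0")
  chk(cfg$design$n_dose_levels >= 2, "design$n_dose_levels must be >= 2")
  chk(length(cfg$design$flies_per_vial) == 2L &&
        cfg$design$flies_per_vial[1] >= 1 &&
        cfg$design$flies_per_vial[2] >= cfg$design$flies_per_vial[1],
      "design$flies_per_vial must be an increasing positive range")
  chk(cfg$sweep$dose_grid$n >= 2 &&
        cfg$sweep$dose_grid$max > cfg$sweep$dose_grid$min &&
        cfg$sweep$dose_grid$min >= 0,
      "sweep$dose_grid must define an increasing non-negative grid")
  chk(cfg$sweep$fecundity_n >= 2, "sweep$fecundity_n must be >= 2")
  chk(cfg$sweep$fecundity_half_width >= 0,
      "sweep$fecundity_half_width must be >= 0")
  chk(all(cfg$sweep$vary %in% c("b_SRSR", "b_SRST", "b_STST")),
      "sweep$vary entries must be b_SRSR, b_SRST or b_STST")
  .report(errors)
  cfg
}
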
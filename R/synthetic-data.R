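#' Ground-truth mortality parameters for the synthetic experiment
#'
#' Logit-linear dose-response truth per genotype-sex class:
#' `logit(d_j) = alpha_j + beta_j * dose`, dose measured (as throughout
#' the package) in ml of an 11.5 ug/ml permethrin-acetone solution
#' applied to the vial. The defaults are the package's calibrated
#' synthetic world: drive-bearing males (SR) and drive-homozygous
#' females (SRSR) have elevated baseline mortality, male curves converge
#' at high dose, mortality spans roughly 0 to 100% over the empirical
#' 0-1.8 ml range, and the wild-type lethal point extrapolates to about
#' 2.3-2.4 ml.
#'
#' @param intercepts named numeric, logit-scale intercept per genotype.
#' @param slopes named numeric, logit units per ml of solution.
#' @param dose_range length-2 numeric, valid dose interval in ml.
#' @return object of class `true_mortality_params`.
#' @export
true_mortality_params <- function(
    intercepts = c(SR = -2.0, ST = -2.5, SRSR = -2.4, SRST = -3.0,
                   STST = -3.0),
    slopes = c(SR = 2.52, ST = 2.8, SRSR = 2.76, SRST = 2.76,
               STST = 2.76),
    dose_range = c(0, 1.8)) {
  if (!all(GENOTYPES %in% names(intercepts)) ||
      !all(GENOTYPES %in% names(slopes))) {
    stop("'intercepts' and 'slopes' must be named over all five genotypes")
  }
  if (!all(is.finite(intercepts[GENOTYPES])) ||
      !all(is.finite(slopes[GENOTYPES]))) {
    stop("mortality parameters must be finite")
  }
  if (length(dose_range) != 2L || dose_range[1] < 0 ||
      dose_range[2] <= dose_range[1]) {
    stop("'dose_range' must be an increasing non-negative interval")
  }
  structure(list(intercepts = intercepts[GENOTYPES],
                 slopes = slopes[GENOTYPES],
                 dose_range = as.numeric(dose_range)),
            class = "true_mortality_params")
}

#' Ground-truth fecundity parameters for the synthetic experiment
#'
#' Poisson log-linear truth per female genotype:
#' `log E(count) = eta_j + gamma * dose + u_vial (+ u_id)`, with
#' `u_vial ~ N(0, sigma_vial^2)` and `u_id ~ N(0, sigma_id^2)`. The
#' default log-means place STST at 40 offspring per brood and offset the
#' other genotypes by the heterosis/drive-cost contrasts measured on the
#' link scale (SRST - STST = 0.384, SRSR - STST = -0.243), so
#' b_SRST > b_STST > b_SRSR. `sigma_id` defaults to 0, matching the
#' negligibly small individual-level variance that motivates the
#' vial-only random-intercept fallback in the fitting module.
#'
#' @param log_means named numeric, log-scale mean count per female
#'   genotype at dose 0 (average vial).
#' @param dose_effect log units per ml of solution.
#' @param sigma_vial standard deviation of vial random intercepts.
#' @param sigma_id standard deviation of individual random intercepts.
#' @return object of class `true_fecundity_params`.
#' @export
true_fecundity_params <- function(
    log_means = c(SRSR = log(40) - 0.243, SRST = log(40) + 0.384,
                  STST = log(40)),
    dose_effect = -0.25, sigma_vial = 0.3, sigma_id = 0) {
  if (!all(FEMALE_GENOTYPES %in% names(log_means))) {
    stop("'log_means' must be named over SRSR, SRST, STST")
  }
  if (!all(is.finite(exp(log_means[FEMALE_GENOTYPES])))) {
    stop("exp(log_means) must be finite")
  }
  if (sigma_vial < 0 || sigma_id < 0) stop("sigma values must be >= 0")
  structure(list(log_means = log_means[FEMALE_GENOTYPES],
                 dose_effect = dose_effect, sigma_vial = sigma_vial,
                 sigma_id = sigma_id),
            class = "true_fecundity_params")
}

#' Generate a vial-level mortality dataset
#'
#' Emulates the pesticide exposure experiment: per genotype,
#' `n_vials_per_genotype` vials receive doses cycled over `dose_values`,
#' each holds a uniform random number of flies in
#' `flies_per_vial_range`, and the 72 h death count is
#' `Binomial(n_exposed, plogis(alpha_j + beta_j * dose))`.
#'
#' @param params a [true_mortality_params()] object.
#' @param n_vials_per_genotype vials per genotype (paper design: 35, for
#'   N = 175 vials over the five genotypes).
#' @param dose_values doses in ml; default an evenly spaced 10-point
#'   grid over `params$dose_range`.
#' @param flies_per_vial_range length-2 integer range (default 7-11).
#' @param seed integer RNG seed (required; all randomness flows from it).
#' @return data.frame with columns `vial_id, genotype, sex, dose_ml,
#'   n_exposed, n_dead`.
#' @export
generate_mortality_dataset <- function(params = true_mortality_params(),
                                       n_vials_per_genotype = 35,
                                       dose_values = NULL,
                                       flies_per_vial_range = c(7, 11),
                                       seed) {
  stopifnot(inherits(params, "true_mortality_params"))
  if (missing(seed)) stop("'seed' is required")
  if (n_vials_per_genotype < 1) stop("'n_vials_per_genotype' must be >= 1")
  if (is.null(dose_values)) {
    dose_values <- seq(params$dose_range[1], params$dose_range[2],
                       length.out = 10)
  }
  if (any(dose_values < 0)) stop("doses must be >= 0")
  if (any(dose_values < params$dose_range[1] - 1e-12) ||
      any(dose_values > params$dose_range[2] + 1e-12)) {
    stop("'dose_values' outside the configured dose_range")
  }
  set.seed(as.integer(seed))
  out <- do.call(rbind, lapply(GENOTYPES, function(g) {
    dose <- rep_len(sort(dose_values), n_vials_per_genotype)
    n_exposed <- sample(seq(flies_per_vial_range[1], flies_per_vial_range[2]),
                        n_vials_per_genotype, replace = TRUE)
    p <- plogis(params$intercepts[g] + params$slopes[g] * dose)
    data.frame(genotype = g, sex = genotype_sex(g), dose_ml = dose,
               n_exposed = n_exposed,
               n_dead = rbinom(n_vials_per_genotype, n_exposed, p),
               stringsAsFactors = FALSE)
  }))
  out <- cbind(vial_id = sprintf("V%04d", seq_len(nrow(out))), out)
  rownames(out) <- NULL
  out
}

#' Generate a per-female fecundity dataset
#'
#' Emulates the fecundity experiment: exposed females (grouped into
#' exposure vials of `females_per_vial`) are scored twice, one week
#' apart, for the number of adult offspring emerging from their laying
#' vial. Counts are Poisson with log-mean
#' `eta_j + gamma * dose + u_vial + u_id`. Because a zero count cannot
#' be distinguished from a failure to mate, zero-count records are
#' removed by default (`drop_zero = TRUE`); females whose records are
#' all zero disappear entirely, which is how the genotype-by-dose
#' sampling gaps of the real experiment arise.
#'
#' @param params a [true_fecundity_params()] object.
#' @param n_females_per_genotype females initially assigned per genotype.
#' @param dose_values doses in ml; default 10 evenly spaced over 0-1.8.
#' @param seed integer RNG seed (required).
#' @param females_per_vial exposure-vial group size (default 5).
#' @param measures fecundity measurements per female (default 2).
#' @param drop_zero remove zero-count records (the experiment's
#'   exclusion rule). Setting `FALSE` keeps them, for testing only.
#' @param survival_thinning optional named vector of per-genotype
#'   retention probabilities emulating genotype-specific survival to
#'   measurement (mirrors the paper's unbalanced realized sample sizes);
#'   default off.
#' @return data.frame with columns `female_id, vial_id, genotype,
#'   dose_ml, measure, offspring` and attribute `n_per_genotype`, the
#'   realized number of females per genotype after exclusions.
#' @export
generate_fecundity_dataset <- function(params = true_fecundity_params(),
                                       n_females_per_genotype = 200,
                                       dose_values = NULL, seed,
                                       females_per_vial = 5, measures = 2,
                                       drop_zero = TRUE,
                                       survival_thinning = NULL) {
  stopifnot(inherits(params, "true_fecundity_params"))
  if (missing(seed)) stop("'seed' is required")
  if (!is.null(dose_values) && length(dose_values) == 0L) {
    stop("'dose_values' must be non-empty")
  }
  if (is.null(dose_values)) dose_values <- seq(0, 1.8, length.out = 10)
  if (any(dose_values < 0)) stop("doses must be >= 0")
  set.seed(as.integer(seed))
  empty <- data.frame(female_id = character(0), vial_id = character(0),
                      genotype = character(0), dose_ml = numeric(0),
                      measure = integer(0), offspring = integer(0),
                      stringsAsFactors = FALSE)
  if (n_females_per_genotype < 1) {
    attr(empty, "n_per_genotype") <- setNames(rep(0L, 3), FEMALE_GENOTYPES)
    return(empty)
  }
  females <- do.call(rbind, lapply(FEMALE_GENOTYPES, function(g) {
    dose <- rep_len(sort(dose_values), n_females_per_genotype)
    data.frame(genotype = g, dose_ml = dose, stringsAsFactors = FALSE)
  }))
  females$female_id <- sprintf("F%05d", seq_len(nrow(females)))
  # exposure vials group consecutive females within a genotype:dose cell
  cell <- paste(females$genotype, females$dose_ml, sep = ":")
  idx_in_cell <- stats::ave(seq_along(cell), cell, FUN = seq_along)
  vial_key <- paste(cell, (idx_in_cell - 1) %/% females_per_vial, sep = "#")
  females$vial_id <- sprintf("FV%04d", as.integer(factor(vial_key,
                                                         levels = unique(vial_key))))
  if (!is.null(survival_thinning)) {
    keep_p <- survival_thinning[females$genotype]
    if (any(is.na(keep_p))) stop("'survival_thinning' must name all female genotypes present")
    females <- females[rbinom(nrow(females), 1L, keep_p) == 1L, , drop = FALSE]
  }
  if (nrow(females) == 0L) {
    attr(empty, "n_per_genotype") <- setNames(rep(0L, 3), FEMALE_GENOTYPES)
    return(empty)
  }
  u_vial <- setNames(rnorm(length(unique(females$vial_id)), 0,
                           params$sigma_vial), unique(females$vial_id))
  u_id <- setNames(rnorm(nrow(females), 0, params$sigma_id),
                   females$female_id)
  out <- do.call(rbind, lapply(seq_len(measures), function(m) {
    lam <- exp(params$log_means[females$genotype] +
                 params$dose_effect * females$dose_ml +
                 u_vial[females$vial_id] + u_id[females$female_id])
    data.frame(female_id = females$female_id, vial_id = females$vial_id,
               genotype = females$genotype, dose_ml = females$dose_ml,
               measure = m, offspring = rpois(nrow(females), lam),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$female_id, out$measure), , drop = FALSE]
  if (drop_zero) out <- out[out$offspring > 0L, , drop = FALSE]
  rownames(out) <- NULL
  n_per <- table(factor(out$genotype[!duplicated(out$female_id)],
                        levels = FEMALE_GENOTYPES))
  attr(out, "n_per_genotype") <- setNames(as.integer(n_per),
                                          FEMALE_GENOTYPES)
  out
}
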
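#' Fit the binomial dose-response mortality model
#'
#' Vial-level death counts are modelled as
#' `cbind(n_dead, n_alive) ~ ...` with a logit link. The default
#' maximal model is `sex + drive_class * dose_ml`, where `drive_class`
#' collapses the five genotype-sex classes onto
#' {wild, het, drive-homozygous}; this is the coding whose term degrees
#' of freedom (genotype 2, sex 1, dose 1, dose x genotype 2) match the
#' empirical analysis the model mirrors. A 5-level genotype factor plus
#' additive sex is rank-deficient (sex is a function of genotype), so it
#' is not offered; `coding = "per_genotype"` instead fits the saturated
#' `0 + genotype + genotype:dose_ml` model with one intercept and one
#' slope per genotype-sex class.
#'
#' @param records vial table as produced by
#'   [generate_mortality_dataset()] / [read_vial_csv()].
#' @param coding `"drive_class"` (default maximal model) or
#'   `"per_genotype"`; or supply `formula` directly.
#' @param formula optional model formula overriding `coding`; may use
#'   the variables `genotype`, `sex`, `drive_class`, `dose_ml`.
#' @return object of class `mortality_fit`: list with the `glm` fit,
#'   the prepared data, `coding`, and a `separation` flag set when
#'   quasi-complete separation is detected (some fitted class fully
#'   dead or alive with a diverging coefficient).
#' @export
fit_mortality_glm <- function(records, coding = c("drive_class",
                                                  "per_genotype"),
                              formula = NULL) {
  if (nrow(records) == 0L) stop("empty mortality table")
  if (length(unique(records$genotype)) < 2L) {
    stop("need >= 2 genotypes to fit the mortality model")
  }
  if (length(unique(records$dose_ml)) < 2L) {
    stop("doses must not all be identical")
  }
  coding <- match.arg(coding)
  d <- records
  d$genotype <- factor(d$genotype, levels = intersect(GENOTYPES,
                                                      unique(d$genotype)))
  d$sex <- factor(genotype_sex(as.character(d$genotype)),
                  levels = intersect(c("female", "male"),
                                     genotype_sex(levels(d$genotype))))
  d$drive_class <- droplevels(drive_class(as.character(d$genotype)))
  d$n_alive <- d$n_exposed - d$n_dead
  if (any(d$n_alive < 0)) stop("n_dead exceeds n_exposed")
  if (is.null(formula)) {
    formula <- if (coding == "drive_class") {
      cbind(n_dead, n_alive) ~ sex + drive_class * dose_ml
    } else {
      cbind(n_dead, n_alive) ~ 0 + genotype + genotype:dose_ml
    }
  } else {
    coding <- "custom"
  }
  fit <- stats::glm(formula, family = stats::binomial("logit"), data = d)
  p_hat <- stats::fitted(fit)
  separation <- any(abs(coef(fit)[!is.na(coef(fit))]) > 12) &&
    (any(p_hat > 1 - 1e-8) || any(p_hat < 1e-8))
  if (separation) {
    warning("possible complete separation: a covariate class is all-dead ",
            "or all-alive and a coefficient diverges")
  }
  structure(list(fit = fit, data = d, coding = coding,
                 formula = formula, separation = separation),
            class = "mortality_fit")
}

#' @export
print.mortality_fit <- function(x, ...) {
  cat("Binomial mortality fit (", x$coding, " coding)\n", sep = "")
  print(coef(x$fit))
  invisible(x)
}

#' @export
logLik.mortality_fit <- function(object, ...) logLik(object$fit)

# accept raw glm/glmer fits or the package wrappers
.unwrap_fit <- function(x) {
  if (inherits(x, c("mortality_fit", "fecundity_fit"))) x$fit else x
}

.term_labels <- function(fit) {
  tt <- if (inherits(fit, "merMod")) {
    terms(fit, fixed.only = TRUE)
  } else {
    terms(fit)
  }
  attr(tt, "term.labels")
}

#' Likelihood-ratio test between nested fits
#'
#' The sequential model-selection primitive: `chisq = 2 * (logLik(full)
#' - logLik(reduced))` on `df = ` difference in parameter count, with
#' the p-value from the upper chi-square tail. The reduced model's
#' fixed terms must be a subset of the full model's.
#'
#' @param full,reduced fitted models (`glm`, `merMod`, or the package's
#'   `mortality_fit`/`fecundity_fit` wrappers); `reduced` nested in
#'   `full`.
#' @return object of class `lrt_result`: list with `dropped` (term
#'   labels present only in the full model), `df`, `chisq`, `p_value`.
#' @export
lrt_drop <- function(full, reduced) {
  ff <- .unwrap_fit(full)
  fr <- .unwrap_fit(reduced)
  lf <- .term_labels(ff)
  lr <- .term_labels(fr)
  if (!all(lr %in% lf)) {
    stop("models are not nested: reduced has terms absent from full")
  }
  llf <- logLik(ff)
  llr <- logLik(fr)
  df <- attr(llf, "df") - attr(llr, "df")
  if (df < 0) stop("models are not nested: reduced has more parameters")
  chisq <- 2 * (as.numeric(llf) - as.numeric(llr))
  if (chisq < -1e-6) {
    warning("negative LRT statistic beyond tolerance; refit advised")
  }
  chisq <- max(chisq, 0)
  p <- if (df == 0L) 1 else pchisq(chisq, df, lower.tail = FALSE)
  structure(list(dropped = setdiff(lf, lr), df = df, chisq = chisq,
                 p_value = p),
            class = "lrt_result")
}

#' @export
print.lrt_result <- function(x, ...) {
  cat(sprintf("LRT drop [%s]: chisq = %.4g, df = %d, p = %.4g\n",
              paste(x$dropped, collapse = ", "), x$chisq, x$df,
              x$p_value))
  invisible(x)
}

#' Fit the Poisson mixed model for fecundity
#'
#' Offspring counts are modelled with a log link, fixed effects for
#' dose, female genotype and (by default) their interaction, and a
#' random intercept for individual nested within exposure vial. When
#' the individual-level variance component collapses to (numerically)
#' zero the fit is singular; the model is then automatically refit with
#' a vial-only random intercept and the `singular` flag is set -- the
#' same fallback the empirical analysis required.
#'
#' @param records fecundity table as produced by
#'   [generate_fecundity_dataset()] / [read_fecundity_csv()].
#' @param random_spec `"auto"` (nested, with fallback), or force
#'   `"individual_in_vial"` / `"vial_only"`.
#' @param fixed right-hand-side of the fixed part as a string,
#'   default `"dose_ml * genotype"`.
#' @return object of class `fecundity_fit`: list with the `glmerMod`
#'   fit, `singular` flag, `random_spec` actually used, and the data.
#' @export
fit_fecundity_mixed <- function(records,
                                random_spec = c("auto",
                                                "individual_in_vial",
                                                "vial_only"),
                                fixed = "dose_ml * genotype") {
  random_spec <- match.arg(random_spec)
  if (nrow(records) == 0L) stop("empty fecundity table")
  if (any(records$offspring < 1L)) {
    stop("offspring counts must be >= 1 (zero-count records are excluded ",
         "upstream)")
  }
  if (length(unique(records$vial_id)) < 2L) stop("need >= 2 vials")
  if (stats::var(records$offspring) == 0) {
    warning("all counts identical; variance components are degenerate")
  }
  d <- records
  d$genotype <- factor(d$genotype,
                       levels = intersect(FEMALE_GENOTYPES,
                                          unique(d$genotype)))
  fit_with <- function(re) {
    f <- as.formula(paste("offspring ~", fixed, "+", re))
    suppressMessages(lme4::glmer(f, data = d, family = stats::poisson("log"),
                                 control = lme4::glmerControl(
                                   calc.derivs = FALSE)))
  }
  singular <- FALSE
  used <- random_spec
  if (random_spec == "vial_only") {
    fit <- fit_with("(1 | vial_id)")
  } else {
    fit <- fit_with("(1 | vial_id) + (1 | vial_id:female_id)")
    vc <- as.data.frame(lme4::VarCorr(fit))
    id_var <- vc$vcov[vc$grp == "vial_id.female_id" |
                        vc$grp == "vial_id:female_id"]
    # "numerically zero": boundary fit, or an individual-level SD below
    # 1% (a negligible multiplicative effect on a Poisson rate)
    singular <- lme4::isSingular(fit, tol = 1e-4) ||
      (length(id_var) == 1L && id_var < 1e-4)
    if (random_spec == "auto" && singular) {
      fit <- fit_with("(1 | vial_id)")
      used <- "vial_only"
    } else {
      used <- "individual_in_vial"
    }
  }
  structure(list(fit = fit, singular = singular, random_spec = used,
                 fixed = fixed, data = d),
            class = "fecundity_fit")
}

#' @export
print.fecundity_fit <- function(x, ...) {
  cat("Poisson GLMM fecundity fit; random spec:", x$random_spec,
      if (x$singular) "(nested fit was singular)" else "", "\n")
  print(lme4::fixef(x$fit))
  invisible(x)
}

#' @export
logLik.fecundity_fit <- function(object, ...) logLik(object$fit)

# p-values for max-|z| over correlated contrasts, by Monte Carlo over
# the (full-rank) marginal-mean covariance; deterministic internal seed,
# caller's RNG state untouched.
.mvt_adjust <- function(abs_z, cmat, mean_cov, se, nsim = 1e5,
                        seed = 20251101L) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  k <- nrow(mean_cov)
  U <- chol(mean_cov + diag(1e-12 * max(diag(mean_cov)), k))
  draws <- crossprod(U, matrix(rnorm(k * nsim), k, nsim)) # k x nsim
  zc <- abs(cmat %*% draws) / se                          # contrasts x nsim
  maxabs <- apply(zc, 2L, max)
  vapply(abs_z, function(z) mean(maxabs >= z), numeric(1))
}

#' Tukey-adjusted pairwise genotype contrasts of marginal means
#'
#' Estimated marginal means per female genotype are computed on the
#' model's link (log) scale by averaging model-matrix rows over a dose
#' grid, mirroring "mean across all exposure concentrations" with equal
#' weights. All pairwise differences are tested with z-tests; the
#' multiplicity adjustment is the exact multivariate-normal max-|z|
#' (Tukey-style) correction, evaluated by Monte Carlo on the joint
#' distribution of the marginal means (no equal-SE studentized-range
#' shortcut), so it remains valid on unbalanced designs.
#'
#' @param fit a `fecundity_fit` (or any fitted model with `fixef`/`coef`
#'   and `vcov` using variables `genotype` and `dose_ml`).
#' @param dose_values dose grid (ml) to average the means over; default
#'   an even 10-point grid over the doses seen by the fit.
#' @return data.frame of class `contrast_result` with one row per
#'   genotype pair: `estimate` (link scale), `se`, `z`, `p_value`,
#'   `p_adjusted` (>= `p_value`), `adjustment = "mvt"`; attribute
#'   `emmeans` holds the per-genotype marginal means.
#' @export
genotype_contrasts <- function(fit, dose_values = NULL) {
  stopifnot(inherits(fit, "fecundity_fit"))
  mod <- fit$fit
  levs <- levels(fit$data$genotype)
  if (length(levs) < 2L) stop("genotype factor needs >= 2 levels")
  if (is.null(dose_values)) {
    r <- range(fit$data$dose_ml)
    dose_values <- if (diff(r) > 0) seq(r[1], r[2], length.out = 10) else r[1]
  }
  tt <- delete.response(terms(mod, fixed.only = TRUE))
  contr <- attr(model.matrix(mod), "contrasts")
  L <- t(vapply(levs, function(g) {
    nd <- data.frame(genotype = factor(g, levels = levs),
                     dose_ml = dose_values)
    colMeans(model.matrix(tt, nd, contrasts.arg = contr))
  }, numeric(length(lme4::fixef(mod)))))
  beta <- lme4::fixef(mod)
  V <- as.matrix(vcov(mod))
  if (rcond(V) < 1e-14) stop("singular coefficient covariance")
  em <- drop(L %*% beta)
  mean_cov <- L %*% V %*% t(L)
  pairs <- utils::combn(seq_along(levs), 2L)
  cmat <- matrix(0, ncol(pairs), length(levs))
  for (j in seq_len(ncol(pairs))) {
    cmat[j, pairs[1, j]] <- 1
    cmat[j, pairs[2, j]] <- -1
  }
  est <- drop(cmat %*% em)
  se <- sqrt(pmax(diag(cmat %*% mean_cov %*% t(cmat)), 0))
  z <- est / se
  p_raw <- 2 * pnorm(-abs(z))
  p_adj <- pmax(.mvt_adjust(abs(z), cmat, mean_cov, se), p_raw)
  out <- data.frame(genotype_1 = levs[pairs[1, ]],
                    genotype_2 = levs[pairs[2, ]],
                    estimate = est, se = se, z = z, p_value = p_raw,
                    p_adjusted = pmin(p_adj, 1), adjustment = "mvt",
                    stringsAsFactors = FALSE)
  attr(out, "emmeans") <- setNames(em, levs)
  class(out) <- c("contrast_result", "data.frame")
  out
}

#' Construct a set of logit-linear dose-response curves
#'
#' Curves map dose to death probability `d = plogis(intercept + slope *
#' dose)`, one per genotype-sex class. Usually produced by
#' [build_dose_response()]; this constructor also lets the ground-truth
#' generator parameters act directly as a parametrization.
#'
#' @param intercepts,slopes named numeric over the five genotypes,
#'   logit scale.
#' @param dose_range valid dose interval (ml); evaluation is permitted
#'   (as extrapolation) beyond it.
#' @return data.frame of class `dose_response_set` with columns
#'   `genotype`, `intercept`, `slope` and attribute `dose_range`.
#' @export
make_dose_response <- function(intercepts, slopes, dose_range = c(0, 1.8)) {
  if (!all(GENOTYPES %in% names(intercepts)) ||
      !all(GENOTYPES %in% names(slopes))) {
    stop("curves required for all five genotypes")
  }
  out <- data.frame(genotype = GENOTYPES,
                    intercept = as.numeric(intercepts[GENOTYPES]),
                    slope = as.numeric(slopes[GENOTYPES]),
                    stringsAsFactors = FALSE)
  attr(out, "dose_range") <- as.numeric(dose_range)
  class(out) <- c("dose_response_set", "data.frame")
  out
}

#' @rdname make_dose_response
#' @param params a [true_mortality_params()] object.
#' @export
as_dose_response <- function(params) {
  stopifnot(inherits(params, "true_mortality_params"))
  make_dose_response(params$intercepts, params$slopes, params$dose_range)
}

#' Death probabilities from a curve set
#'
#' @param curves a `dose_response_set`.
#' @param dose scalar dose in ml (>= 0).
#' @return named numeric over [GENOTYPES], each in `[0, 1]`.
#' @export
death_prob <- function(curves, dose) {
  stopifnot(inherits(curves, "dose_response_set"))
  if (dose < 0) stop("dose must be >= 0")
  setNames(plogis(curves$intercept + curves$slope * dose),
           curves$genotype)
}

#' Extract per-genotype mortality reaction norms from a fitted model
#'
#' The coupling between the statistical and dynamical halves of the
#' pipeline: the curves evaluate to the fitted model's predicted means
#' exactly (same link, same coefficients), so the simulation's death
#' probability d_(i,j) for genotype j at dose i is the model's
#' prediction, not an approximation. Because dose enters every offered
#' formula linearly on the logit scale, each class's prediction is
#' itself logit-linear; intercept and slope are read off the linear
#' predictor at doses 0 and 1.
#'
#' @param fit a `mortality_fit`.
#' @return a [make_dose_response()] set with one curve per genotype.
#' @export
build_dose_response <- function(fit) {
  stopifnot(inherits(fit, "mortality_fit"))
  present <- levels(fit$data$genotype)
  missing <- setdiff(GENOTYPES, present)
  if (length(missing) > 0L) {
    stop("missing genotype level(s) in fit: ",
         paste(missing, collapse = ", "))
  }
  eta <- function(g, dose) {
    nd <- data.frame(genotype = factor(g, levels = present),
                     dose_ml = dose, stringsAsFactors = FALSE)
    nd$sex <- factor(genotype_sex(g), levels = levels(fit$data$sex))
    nd$drive_class <- factor(as.character(drive_class(g)),
                             levels = levels(fit$data$drive_class))
    unname(predict(fit$fit, newdata = nd, type = "link"))
  }
  e0 <- vapply(GENOTYPES, eta, numeric(1), dose = 0)
  e1 <- vapply(GENOTYPES, eta, numeric(1), dose = 1)
  make_dose_response(e0, e1 - e0,
                     dose_range = range(fit$data$dose_ml))
}

#' Predicted mortality with delta-method confidence bands
#'
#' Predictions on the probability scale with pointwise intervals formed
#' on the link scale (estimate +/- z * SE) and back-transformed.
#'
#' @param fit a `mortality_fit`.
#' @param genotype genotype token.
#' @param dose numeric vector of doses (ml).
#' @param level confidence level.
#' @return data.frame `dose_ml, fit, lwr, upr`.
#' @export
predict_mortality <- function(fit, genotype, dose, level = 0.95) {
  stopifnot(inherits(fit, "mortality_fit"))
  nd <- data.frame(genotype = factor(genotype,
                                     levels = levels(fit$data$genotype)),
                   dose_ml = dose, stringsAsFactors = FALSE)
  nd$sex <- factor(genotype_sex(genotype), levels = levels(fit$data$sex))
  nd$drive_class <- factor(as.character(drive_class(genotype)),
                           levels = levels(fit$data$drive_class))
  pr <- predict(fit$fit, newdata = nd, type = "link", se.fit = TRUE)
  zq <- stats::qnorm(1 - (1 - level) / 2)
  data.frame(dose_ml = dose, fit = plogis(pr$fit),
             lwr = plogis(pr$fit - zq * pr$se.fit),
             upr = plogis(pr$fit + zq * pr$se.fit))
}

#' Brood-size parameters from fecundity records
#'
#' The brood size b_j for each female genotype is the arithmetic mean
#' offspring count over all of that genotype's records (all doses
#' pooled), and the sweep range is that median value +/- `half_width`
#' offspring -- the "natural variation" band explored by the
#' equilibrium sweeps.
#'
#' @param records fecundity table.
#' @param half_width sweep half-width in offspring (default 10).
#' @return object of class `fecundity_params`: list with `b` (named
#'   over SRSR, SRST, STST), `half_width`, and `ranges` (2 x 3, floored
#'   at 0).
#' @export
build_fecundity_params <- function(records, half_width = 10) {
  missing <- setdiff(FEMALE_GENOTYPES, unique(records$genotype))
  if (length(missing) > 0L) {
    stop("no fecundity records for genotype(s): ",
         paste(missing, collapse = ", "))
  }
  b <- vapply(FEMALE_GENOTYPES, function(g) {
    mean(records$offspring[records$genotype == g])
  }, numeric(1))
  fecundity_params(b, half_width = half_width)
}

#' @rdname build_fecundity_params
#' @param b named numeric brood sizes over SRSR, SRST, STST (all >= 0).
#' @export
fecundity_params <- function(b, half_width = 10) {
  if (!all(FEMALE_GENOTYPES %in% names(b))) {
    stop("'b' must be named over SRSR, SRST, STST")
  }
  b <- b[FEMALE_GENOTYPES]
  if (any(b < 0)) stop("brood sizes must be >= 0")
  if (half_width < 0) stop("'half_width' must be >= 0")
  ranges <- rbind(lo = pmax(b - half_width, 0), hi = b + half_width)
  structure(list(b = b, half_width = half_width, ranges = ranges),
            class = "fecundity_params")
}

#' @export
print.fecundity_params <- function(x, ...) {
  cat("Brood sizes (offspring per brood):\n")
  print(round(x$b, 3))
  cat("sweep half-width:", x$half_width, "\n")
  invisible(x)
}
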
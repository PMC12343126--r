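#' Population state of the five-genotype model
#'
#' Abundances are continuous, non-negative densities (the model is
#' deterministic); `t` is the generation index.
#'
#' @param abundance named numeric over [GENOTYPES] (any order; missing
#'   names are an error).
#' @param t generation index (>= 0).
#' @return object of class `population_state`: list with `n` (named in
#'   canonical order) and `t`.
#' @export
population_state <- function(abundance, t = 0) {
  if (!all(GENOTYPES %in% names(abundance))) {
    stop("'abundance' must be named over all five genotypes")
  }
  n <- as.numeric(abundance[GENOTYPES])
  names(n) <- GENOTYPES
  if (any(!is.finite(n)) || any(n < 0)) {
    stop("abundances must be finite and >= 0")
  }
  if (t < 0) stop("'t' must be >= 0")
  structure(list(n = n, t = as.integer(t)), class = "population_state")
}

#' @export
print.population_state <- function(x, ...) {
  cat(sprintf("generation %d, total %.4g\n", x$t, sum(x$n)))
  print(round(x$n, 4))
  invisible(x)
}

#' Default initial population state
#'
#' Total density `n_total` at a 1:1 sex ratio, with the SR-male, SRSR-
#' and SRST-female frequencies configurable. The defaults introduce the
#' driver at moderate male frequency with females near Hardy-Weinberg
#' proportions for allele frequency 0.1.
#'
#' @param n_total total initial density.
#' @param sr_male_freq initial frequency of SR among males.
#' @param srsr_freq,srst_freq initial SRSR and SRST frequencies among
#'   females (remainder STST).
#' @return a [population_state()] at `t = 0`.
#' @export
init_state <- function(n_total = 1000, sr_male_freq = 0.1,
                       srsr_freq = 0.01, srst_freq = 0.18) {
  if (srsr_freq + srst_freq > 1 || min(sr_male_freq, srsr_freq,
                                       srst_freq) < 0 ||
      sr_male_freq > 1) {
    stop("initial frequencies must be proportions with SRSR + SRST <= 1")
  }
  m <- n_total / 2
  f <- n_total / 2
  population_state(c(SR = m * sr_male_freq, ST = m * (1 - sr_male_freq),
                     SRSR = f * srsr_freq, SRST = f * srst_freq,
                     STST = f * (1 - srsr_freq - srst_freq)))
}

#' Parameter bundle for the drive model
#'
#' @param curves a `dose_response_set` giving d_(i,j).
#' @param fecundity a [fecundity_params()] object giving b_j.
#' @param theta strength of Beverton-Holt density dependence (> 0); the
#'   default places the pesticide-free wild-type equilibrium at the
#'   initial density: `theta = (1 - 2 / b_STST) / n_total`.
#' @param init initial [population_state()].
#' @param t_max horizon; the frequency at `t_max` (default 1000) is
#'   taken as the equilibrium frequency.
#' @param epsilon extinction threshold in density units; default 1e-6
#'   of the initial total density. A population is flagged extinct when
#'   either the total density or the total male density falls below
#'   `epsilon` (a male-less population cannot reproduce).
#' @param efficacy drive efficacy, fixed at 1 in production; other
#'   values are a test-only hook.
#' @return object of class `model_params`.
#' @export
model_params <- function(curves, fecundity, theta = NULL,
                         init = init_state(), t_max = 1000,
                         epsilon = NULL, efficacy = 1) {
  stopifnot(inherits(curves, "dose_response_set"),
            inherits(fecundity, "fecundity_params"),
            inherits(init, "population_state"))
  if (is.null(theta)) {
    b <- unname(fecundity$b["STST"])
    if (b <= 2) stop("default theta requires b_STST > 2")
    theta <- (1 - 2 / b) / sum(init$n)
  }
  if (theta <= 0) stop("'theta' must be > 0")
  if (is.null(epsilon)) epsilon <- 1e-6 * sum(init$n)
  if (epsilon <= 0) stop("'epsilon' must be > 0")
  if (t_max < 1) stop("'t_max' must be >= 1")
  if (efficacy < 0 || efficacy > 1) stop("'efficacy' must be in [0, 1]")
  structure(list(curves = curves, fecundity = fecundity, theta = theta,
                 init = init, t_max = as.integer(t_max),
                 epsilon = epsilon, efficacy = efficacy),
            class = "model_params")
}

#' Pre-mating pesticide mortality
#'
#' Each genotype's abundance is multiplied by its dose-specific
#' survival probability `1 - d_(dose,j)`; deterministic.
#'
#' @param state a [population_state()].
#' @param dose dose in ml (>= 0).
#' @param curves a `dose_response_set`.
#' @return the thinned [population_state()] (same generation index).
#' @export
apply_mortality <- function(state, dose, curves) {
  stopifnot(inherits(state, "population_state"))
  d <- death_prob(curves, dose)
  population_state(state$n * (1 - d[GENOTYPES]), t = state$t)
}

#' Random mating and reproduction
#'
#' Females mate exactly once; mate choice is proportional to male
#' relative abundance. A female of genotype j produces a brood of b_j
#' offspring regardless of sire (drive kills Y sperm, it does not
#' shrink the brood), distributed over offspring genotypes by
#' [cross_offspring()]. If the male population is zero, no offspring
#' are produced.
#'
#' @param state post-mortality [population_state()].
#' @param fecundity a [fecundity_params()] object.
#' @param efficacy drive efficacy (production value 1).
#' @return named numeric vector of offspring abundances per genotype.
#' @export
mate_and_reproduce <- function(state, fecundity, efficacy = 1) {
  stopifnot(inherits(state, "population_state"),
            inherits(fecundity, "fecundity_params"))
  if (any(state$n < 0)) stop("abundances must be >= 0")
  cm <- cross_matrix(efficacy)
  .reproduce_kernel(state$n, fecundity$b, cm)
}

# inner kernel shared with simulate_drive(); n in canonical order,
# b over females, cm from cross_matrix()
.reproduce_kernel <- function(n, b, cm) {
  m <- n[1:2]
  mt <- m[1L] + m[2L]
  if (mt <= 0) {
    return(setNames(numeric(5L), GENOTYPES))
  }
  w <- rep.int(m / mt, 3L) * rep(n[3:5] * b, each = 2L)
  setNames(drop(crossprod(cm, w)), GENOTYPES)
}

#' Beverton-Holt density regulation
#'
#' Every genotype's offspring abundance is multiplied by the common
#' recruitment factor `1 / (1 + theta * N_offspring)`, so genotype
#' proportions are unchanged and the recruited total is bounded above
#' by `1 / theta`.
#'
#' @param offspring named offspring abundances.
#' @param theta density-dependence strength (> 0).
#' @return regulated abundances.
#' @export
density_regulate <- function(offspring, theta) {
  if (theta <= 0) stop("'theta' must be > 0")
  tot <- sum(offspring)
  if (tot <= 0) return(offspring)
  offspring / (1 + theta * tot)
}

#' One generation of the drive model
#'
#' Non-overlapping generations: pesticide mortality, then random mating
#' and reproduction, then density-dependent recruitment; adults do not
#' persist.
#'
#' @param state a [population_state()].
#' @param dose dose in ml.
#' @param params a [model_params()] object.
#' @return the next [population_state()] (`t + 1`).
#' @export
drive_step <- function(state, dose, params) {
  stopifnot(inherits(params, "model_params"))
  surv <- apply_mortality(state, dose, params$curves)
  off <- mate_and_reproduce(surv, params$fecundity, params$efficacy)
  population_state(density_regulate(off, params$theta), t = state$t + 1L)
}

#' Frequency of SR among males / of SRSR among females
#'
#' Returns `NaN` (the undefined sentinel) when the relevant denominator
#' is zero.
#'
#' @param state a [population_state()] or a named abundance vector.
#' @return proportion in `[0, 1]`, or `NaN`.
#' @export
sr_male_frequency <- function(state) {
  n <- if (inherits(state, "population_state")) state$n else state
  mt <- n[["SR"]] + n[["ST"]]
  if (mt <= 0) NaN else n[["SR"]] / mt
}

#' @rdname sr_male_frequency
#' @export
srsr_female_frequency <- function(state) {
  n <- if (inherits(state, "population_state")) state$n else state
  ft <- n[["SRSR"]] + n[["SRST"]] + n[["STST"]]
  if (ft <= 0) NaN else n[["SRSR"]] / ft
}

#' Simulate the drive model to the equilibrium horizon
#'
#' Iterates [drive_step()] for `params$t_max` generations at a fixed
#' dose, recording per-generation abundances, total density, SR-male
#' frequency and SRSR-female frequency. Simulation stops early, with
#' the `extinct` attribute set, when the total density or the total
#' male density drops below `params$epsilon`.
#'
#' @param params a [model_params()] object.
#' @param dose dose in ml.
#' @return data.frame trajectory with columns `t, n_SR, n_ST, n_SRSR,
#'   n_SRST, n_STST, total, sr_male_freq, srsr_female_freq`;
#'   attributes `extinct` (logical), `t_final`, `dose`.
#' @export
simulate_drive <- function(params, dose) {
  stopifnot(inherits(params, "model_params"))
  d <- death_prob(params$curves, dose)[GENOTYPES]
  surv_frac <- 1 - d
  b <- params$fecundity$b[FEMALE_GENOTYPES]
  cm <- cross_matrix(params$efficacy)
  theta <- params$theta
  eps <- params$epsilon
  t_max <- params$t_max
  n <- params$init$n
  traj <- matrix(NA_real_, t_max + 1L, 9L)
  colnames(traj) <- c("t", paste0("n_", GENOTYPES), "total",
                      "sr_male_freq", "srsr_female_freq")
  rec <- function(row, t, n) {
    mt <- n[1L] + n[2L]
    ft <- n[3L] + n[4L] + n[5L]
    traj[row, ] <<- c(t, n, sum(n),
                      if (mt > 0) n[1L] / mt else NaN,
                      if (ft > 0) n[3L] / ft else NaN)
  }
  rec(1L, 0, n)
  extinct <- sum(n) < eps || (n[1L] + n[2L]) < eps
  t_final <- 0L
  if (!extinct) {
    for (t in seq_len(t_max)) {
      s <- n * surv_frac
      off <- .reproduce_kernel(s, b, cm)
      tot <- sum(off)
      n <- if (tot > 0) off / (1 + theta * tot) else off
      rec(t + 1L, t, n)
      t_final <- t
      if (sum(n) < eps || (n[1L] + n[2L]) < eps) {
        extinct <- TRUE
        break
      }
    }
  }
  out <- as.data.frame(traj[seq_len(t_final + 1L), , drop = FALSE])
  attr(out, "extinct") <- extinct
  attr(out, "t_final") <- t_final
  attr(out, "dose") <- dose
  out
}
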
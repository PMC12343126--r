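.vial_header <- c("vial_id", "genotype", "sex", "dose_ml", "n_exposed",
                  "n_dead")
.fec_header <- c("female_id", "vial_id", "genotype", "dose_ml",
                 "measure", "offspring")

.check_header <- function(path, expected) {
  got <- names(read.csv(path, nrows = 1, check.names = FALSE))
  if (nrow(read.csv(path)) == 0L) {
    got <- strsplit(readLines(path, n = 1L), ",", fixed = TRUE)[[1L]]
  }
  if (!identical(got, expected)) {
    stop("malformed header in ", path, ": expected '",
         paste(expected, collapse = ","), "', got '",
         paste(got, collapse = ","), "'")
  }
}

.report <- function(errors) {
  if (length(errors) > 0L) {
    stop("validation failed:\n  ", paste(errors, collapse = "\n  "))
  }
}

#' Read / write the vial-level mortality CSV
#'
#' Flat CSV dialect `vial_id,genotype,sex,dose_ml,n_exposed,n_dead`;
#' genotype tokens restricted to the five classes, counts checked with
#' `0 <= n_dead <= n_exposed`, doses `>= 0`. Every violated row is
#' reported with its line number (header = line 1).
#'
#' @param path file path.
#' @return validated data.frame of vial records.
#' @export
read_vial_csv <- function(path) {
  .check_header(path, .vial_header)
  d <- read.csv(path, colClasses = c("character", "character", "character",
                                     "numeric", "integer", "integer"))
  errors <- character(0)
  line <- seq_len(nrow(d)) + 1L
  bad <- !(d$genotype %in% GENOTYPES)
  if (any(bad)) {
    errors <- c(errors, sprintf("line %d: unknown genotype token '%s'",
                                line[bad], d$genotype[bad]))
  }
  bad2 <- !bad & d$sex != genotype_sex(ifelse(bad, "SR", d$genotype))
  if (any(bad2)) {
    errors <- c(errors, sprintf("line %d: sex '%s' inconsistent with genotype '%s'",
                                line[bad2], d$sex[bad2], d$genotype[bad2]))
  }
  bad <- is.na(d$dose_ml) | d$dose_ml < 0
  if (any(bad)) {
    errors <- c(errors, sprintf("line %d: dose_ml must be >= 0", line[bad]))
  }
  bad <- is.na(d$n_exposed) | is.na(d$n_dead) | d$n_dead < 0 |
    d$n_dead > d$n_exposed
  if (any(bad)) {
    errors <- c(errors,
                sprintf("line %d: need 0 <= n_dead <= n_exposed", line[bad]))
  }
  .report(errors)
  d
}

#' @rdname read_vial_csv
#' @param records vial table to write.
#' @export
write_vial_csv <- function(records, path) {
  write.csv(records[, .vial_header], path, row.names = FALSE,
            quote = FALSE)
  invisible(path)
}

#' Read / write the per-female fecundity CSV
#'
#' Flat CSV dialect `female_id,vial_id,genotype,dose_ml,measure,
#' offspring`; female genotypes only, `measure` in {1, 2}, counts
#' `>= 1` (zero-count records are excluded upstream by design). Every
#' violated row is reported with its line number.
#'
#' @param path file path.
#' @return validated data.frame of fecundity records.
#' @export
read_fecundity_csv <- function(path) {
  .check_header(path, .fec_header)
  d <- read.csv(path, colClasses = c("character", "character", "character",
                                     "numeric", "integer", "integer"))
  errors <- character(0)
  line <- seq_len(nrow(d)) + 1L
  bad <- !(d$genotype %in% FEMALE_GENOTYPES)
  if (any(bad)) {
    errors <- c(errors, sprintf("line %d: unknown female genotype token '%s'",
                                line[bad], d$genotype[bad]))
  }
  bad <- is.na(d$dose_ml) | d$dose_ml < 0
  if (any(bad)) {
    errors <- c(errors, sprintf("line %d: dose_ml must be >= 0", line[bad]))
  }
  bad <- is.na(d$measure) | !(d$measure %in% c(1L, 2L))
  if (any(bad)) {
    errors <- c(errors, sprintf("line %d: measure must be 1 or 2", line[bad]))
  }
  bad <- is.na(d$offspring) | d$offspring < 1L
  if (any(bad)) {
    errors <- c(errors,
                sprintf("line %d: offspring must be >= 1 after exclusion",
                        line[bad]))
  }
  n_meas <- table(d$female_id)
  if (any(n_meas > 2L)) {
    errors <- c(errors, sprintf("female '%s' has %d measurements (max 2)",
                                names(n_meas)[n_meas > 2L],
                                as.integer(n_meas[n_meas > 2L])))
  }
  .report(errors)
  d
}

#' @rdname read_fecundity_csv
#' @param records fecundity table to write.
#' @export
write_fecundity_csv <- function(records, path) {
  write.csv(records[, .fec_header], path, row.names = FALSE,
            quote = FALSE)
  invisible(path)
}

#' Read / write the model parametrization file
#'
#' JSON file carrying everything the drive model consumes: the five
#' logit-linear mortality curves, brood sizes with sweep half-width,
#' theta, the initial state, horizon, extinction threshold and drive
#' efficacy. The file written by the fitting stage is consumed verbatim
#' by the simulation stage.
#'
#' @param params a [model_params()] object.
#' @param path file path.
#' @return `write_params_file` returns the path invisibly;
#'   `read_params_file` returns the reconstructed [model_params()].
#' @export
write_params_file <- function(params, path) {
  stopifnot(inherits(params, "model_params"))
  obj <- list(
    curves = list(genotype = params$curves$genotype,
                  intercept = params$curves$intercept,
                  slope = params$curves$slope,
                  dose_range = attr(params$curves, "dose_range")),
    fecundity = list(b = as.list(params$fecundity$b),
                     half_width = params$fecundity$half_width),
    theta = params$theta,
    init = as.list(params$init$n),
    t_max = params$t_max,
    epsilon = params$epsilon,
    efficacy = params$efficacy)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_params_file
#' @export
read_params_file <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  curves <- make_dose_response(
    setNames(obj$curves$intercept, obj$curves$genotype),
    setNames(obj$curves$slope, obj$curves$genotype),
    dose_range = obj$curves$dose_range)
  fec <- fecundity_params(unlist(obj$fecundity$b),
                          half_width = obj$fecundity$half_width)
  init <- population_state(unlist(obj$init))
  model_params(curves, fec, theta = obj$theta, init = init,
               t_max = obj$t_max, epsilon = obj$epsilon,
               efficacy = obj$efficacy)
}
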
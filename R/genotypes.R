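#' srdrive: sex-ratio meiotic drive dynamics under pesticide stress
#'
#' Synthetic dose-response and fecundity experiments, GLM/GLMM
#' parametrization, and a deterministic five-genotype model of X-linked
#' sex-ratio drive iterated to equilibrium.
#'
#' @importFrom stats plogis qlogis rbinom rpois rnorm runif pchisq pnorm
#'   coef vcov logLik predict model.matrix terms delete.response setNames
#'   as.formula formula aggregate reformulate
#' @importFrom utils read.csv write.csv packageVersion modifyList
#' @keywords internal
"_PACKAGE"

#' Genotype classes of the X-linked drive system
#'
#' Males are hemizygous and carry a single X allele (`SR` or `ST`);
#' females carry two (`SRSR`, `SRST`, `STST`). These five tokens are the
#' only valid genotype labels throughout the package.
#'
#' @format Character vectors.
#' @export
GENOTYPES <- c("SR", "ST", "SRSR", "SRST", "STST")

#' @rdname GENOTYPES
#' @export
MALE_GENOTYPES <- c("SR", "ST")

#' @rdname GENOTYPES
#' @export
FEMALE_GENOTYPES <- c("SRSR", "SRST", "STST")

#' Sex implied by a genotype label
#'
#' @param genotype character vector of genotype tokens.
#' @return `"male"` or `"female"` for each element.
#' @export
genotype_sex <- function(genotype) {
  bad <- setdiff(unique(genotype), GENOTYPES)
  if (length(bad) > 0L) {
    stop("unknown genotype token(s): ", paste(bad, collapse = ", "))
  }
  ifelse(genotype %in% MALE_GENOTYPES, "male", "female")
}

#' Drive class of a genotype (wild / heterozygous / drive-homozygous)
#'
#' Collapses the five genotype-sex classes onto the three drive classes
#' used by the mortality model: `wild` (ST males, STST females), `het`
#' (SRST females) and `drive` (SR males, SRSR females).
#'
#' @inheritParams genotype_sex
#' @return factor with levels `wild`, `het`, `drive`.
#' @export
drive_class <- function(genotype) {
  genotype_sex(genotype) # validates tokens
  cls <- c(SR = "drive", ST = "wild", SRSR = "drive", SRST = "het",
           STST = "wild")[genotype]
  factor(unname(cls), levels = c("wild", "het", "drive"))
}

# dam genotype -> the two transmissible X alleles
.dam_alleles <- list(SRSR = c("SR", "SR"), SRST = c("SR", "ST"),
                     STST = c("ST", "ST"))

.daughter_genotype <- function(sire_allele, dam_allele) {
  a <- sort(c(sire_allele, dam_allele)) # "SR" < "ST"
  paste0(a[1L], a[2L])
}

#' Offspring genotype distribution of a single cross
#'
#' Implements X-linked inheritance with sex-ratio drive acting in sires:
#' an SR sire's Y-bearing sperm are destroyed with probability `efficacy`
#' (the gamete pool is renormalized, so brood size is unaffected). At the
#' production default `efficacy = 1` an SR sire produces all-daughter
#' broods, every daughter inheriting his SR allele; ST sires give the
#' Mendelian 1:1 sex ratio. Dams transmit each of their two X alleles
#' with probability 1/2; sons receive only the maternal allele.
#'
#' @param sire male genotype, `"SR"` or `"ST"`.
#' @param dam female genotype, `"SRSR"`, `"SRST"` or `"STST"`.
#' @param efficacy probability that a Y-bearing sperm is killed in an SR
#'   sire. Fixed at 1 in production parametrizations; values < 1 are a
#'   test-only hook.
#' @return object of class `cross_outcome`: list with `sire`, `dam` and
#'   `offspring`, a named probability vector over [GENOTYPES] summing
#'   to 1.
#' @examples
#' cross_offspring("SR", "STST")$offspring  # all SRST daughters
#' @export
cross_offspring <- function(sire, dam, efficacy = 1) {
  if (!(is.character(sire) && length(sire) == 1L && sire %in% MALE_GENOTYPES)) {
    stop("'sire' must be one of ", paste(MALE_GENOTYPES, collapse = ", "))
  }
  if (!(is.character(dam) && length(dam) == 1L && dam %in% FEMALE_GENOTYPES)) {
    stop("'dam' must be one of ", paste(FEMALE_GENOTYPES, collapse = ", "))
  }
  if (!is.numeric(efficacy) || efficacy < 0 || efficacy > 1) {
    stop("'efficacy' must be in [0, 1]")
  }
  y_surv <- if (sire == "SR") 1 - efficacy else 1
  daughter_share <- 1 / (1 + y_surv)
  son_share <- y_surv / (1 + y_surv)
  off <- setNames(numeric(5L), GENOTYPES)
  for (a in .dam_alleles[[dam]]) {
    dg <- .daughter_genotype(sire, a)
    off[dg] <- off[dg] + 0.5 * daughter_share
    off[a] <- off[a] + 0.5 * son_share # son genotype = maternal allele
  }
  structure(list(sire = sire, dam = dam, offspring = off),
            class = "cross_outcome")
}

#' @export
print.cross_outcome <- function(x, ...) {
  cat(sprintf("cross %s x %s:\n", x$sire, x$dam))
  print(round(x$offspring[x$offspring > 0], 4))
  invisible(x)
}

#' Full mating table as a matrix
#'
#' All six sire-by-dam crosses, one row per cross, columns the five
#' offspring genotypes. Row order is sire-major within dam:
#' `SR:SRSR, ST:SRSR, SR:SRST, ST:SRST, SR:STST, ST:STST`.
#'
#' @inheritParams cross_offspring
#' @return 6 x 5 numeric matrix; each row sums to 1.
#' @export
cross_matrix <- function(efficacy = 1) {
  rows <- expand.grid(sire = MALE_GENOTYPES, dam = FEMALE_GENOTYPES,
                      stringsAsFactors = FALSE)
  m <- t(mapply(function(s, d) cross_offspring(s, d, efficacy)$offspring,
                rows$sire, rows$dam))
  dimnames(m) <- list(paste(rows$sire, rows$dam, sep = ":"), GENOTYPES)
  m
}
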
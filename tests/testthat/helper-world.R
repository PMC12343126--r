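# Shared fixtures, all generated in code.

# the calibrated synthetic world used throughout the suite
world_params <- function(t_max = 1000, ...) {
  model_params(as_dose_response(true_mortality_params()),
               fecundity_params(exp(true_fecundity_params()$log_means)),
               t_max = t_max, ...)
}

# flat curves: same constant death probability d for every genotype
flat_curves <- function(d) {
  make_dose_response(setNames(rep(qlogis(d), 5), GENOTYPES),
                     setNames(rep(0, 5), GENOTYPES),
                     dose_range = c(0, 2.5))
}

equal_fecundity <- function(b = 20) {
  fecundity_params(setNames(rep(b, 3), FEMALE_GENOTYPES))
}

# independent mating-table oracle: the six cross distributions written
# out by hand (Mendelian X-linked segregation + 100%-efficacy drive),
# not derived from cross_offspring()
hand_mating_table <- function() {
  m <- matrix(0, 6, 5,
              dimnames = list(c("SR:SRSR", "ST:SRSR", "SR:SRST",
                                "ST:SRST", "SR:STST", "ST:STST"),
                              c("SR", "ST", "SRSR", "SRST", "STST")))
  m["SR:SRSR", "SRSR"] <- 1
  m["ST:SRSR", c("SR", "SRST")] <- 1 / 2
  m["SR:SRST", c("SRSR", "SRST")] <- 1 / 2
  m["ST:SRST", c("SR", "ST", "SRST", "STST")] <- 1 / 4
  m["SR:STST", "SRST"] <- 1
  m["ST:STST", c("ST", "STST")] <- 1 / 2
  m
}

# brute-force reproduction oracle: explicit double sum over the six
# crosses using the hand table
enumerate_offspring <- function(n, b) {
  tab <- hand_mating_table()
  males <- n[c("SR", "ST")]
  mt <- sum(males)
  out <- setNames(numeric(5), colnames(tab))
  if (mt <= 0) return(out)
  for (dam in c("SRSR", "SRST", "STST")) {
    for (sire in c("SR", "ST")) {
      w <- n[[dam]] * b[[dam]] * males[[sire]] / mt
      out <- out + w * tab[paste(sire, dam, sep = ":"), ]
    }
  }
  out
}

random_state <- function() {
  population_state(setNames(runif(5, 0, 100), GENOTYPES))
}

small_pipeline_config <- function(outdir, seed = 99L) {
  list(seed = seed, output_dir = outdir,
       design = list(n_vials_per_genotype = 15L,
                     n_females_per_genotype = 45L,
                     n_dose_levels = 5L),
       model = list(t_max = 200L),
       sweep = list(dose_grid = list(n = 6L), fecundity_n = 3L,
                    vary = c("b_SRSR")))
}
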
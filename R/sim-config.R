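#' Demographic configuration
#'
#' A piecewise-constant diploid population-size trajectory applied
#' oldest-first after the burn-in, with partial self-fertilization and a
#' present-day sample.
#'
#' @param epochs list of `c(duration_generations, diploid_N)` pairs, or a
#'   data.frame with columns `duration` and `N`, oldest first.
#' @param selfing_rate per-offspring probability of self-fertilization.
#' @param sample_size diploid individuals sampled at present; must not exceed
#'   the final epoch's N.
#' @param seed integer RNG seed (the stable population's seed drives the
#'   whole paired simulation).
#' @param generation_time generation time in years, kept as metadata (the
#'   species these simulations emulate has g = 10 years).
#' @return An object of class `demography_config`.
#' @export
demography_config <- function(epochs, selfing_rate = 0, sample_size,
                              seed = NULL, generation_time = 10) {
  if (is.data.frame(epochs)) {
    ep <- data.frame(duration = as.integer(epochs$duration),
                     N = as.integer(epochs$N))
  } else {
    if (length(epochs) == 0) stop("epoch schedule is empty")
    ep <- data.frame(duration = vapply(epochs, function(e) as.integer(e[1]),
                                       integer(1)),
                     N = vapply(epochs, function(e) as.integer(e[2]),
                                integer(1)))
  }
  if (nrow(ep) == 0) stop("epoch schedule is empty")
  if (any(ep$N < 2)) stop("every diploid_N must be >= 2")
  if (any(ep$duration < 1)) stop("every epoch duration must be >= 1")
  if (selfing_rate < 0 || selfing_rate > 1)
    stop("selfing_rate must be in [0, 1]")
  if (sample_size > ep$N[nrow(ep)])
    stop("sample_size exceeds the final diploid_N")
  structure(list(epochs = ep, selfing_rate = selfing_rate,
                 sample_size = as.integer(sample_size), seed = seed,
                 generation_time = generation_time),
            class = "demography_config")
}

#' Mutation model with effect classes
#'
#' Mutations fall into four classes: `SYN` (neutral; stands in for all
#' selectively neutral variation and is placed uniformly over the genome),
#' `TOL` (tolerated missense), `DEL` (deleterious missense) and `LOF`
#' (loss of function). The three coding-effect classes are placed on
#' zero-fold degenerate coding sites so downstream category logic sees
#' amino-acid-changing positions. Fitness is multiplicative across sites
#' with genotype weights 1, 1 + hs, 1 + s.
#'
#' @param mu per-site per-generation mutation rate. The default is the rate
#'   estimated for the ironwood genomes these simulations emulate.
#' @param class_fractions probabilities over SYN/TOL/DEL/LOF, summing to 1.
#' @param selection named selection coefficients (s <= 0; exactly 0 for SYN).
#' @param dominance named dominance coefficients in [0, 1].
#' @return An object of class `mutation_model`.
#' @export
mutation_model <- function(mu = 2.182e-8,
                           class_fractions = c(SYN = 0.80, TOL = 0.06,
                                               DEL = 0.10, LOF = 0.04),
                           selection = c(SYN = 0, TOL = -1e-4,
                                         DEL = -1e-2, LOF = -0.2),
                           dominance = c(SYN = 0.5, TOL = 0.3,
                                         DEL = 0.2, LOF = 0.02)) {
  classes <- c("SYN", "TOL", "DEL", "LOF")
  stopifnot(all(classes %in% names(class_fractions)),
            all(classes %in% names(selection)),
            all(classes %in% names(dominance)))
  class_fractions <- class_fractions[classes]
  selection <- selection[classes]
  dominance <- dominance[classes]
  if (abs(sum(class_fractions) - 1) > 1e-12)
    stop("class_fractions must sum to 1")
  if (selection[["SYN"]] != 0) stop("SYN selection coefficient must be 0")
  if (any(selection > 0)) stop("selection coefficients must be <= 0")
  if (any(dominance < 0 | dominance > 1))
    stop("dominance coefficients must be in [0, 1]")
  structure(list(mu = mu, class_fractions = class_fractions,
                 selection = selection, dominance = dominance,
                 classes = classes),
            class = "mutation_model")
}

#' Default two-population study conditions
#'
#' The conditions under which the package's synthetic contrasts are run: a
#' 2 Mb genome (4 x 500 kb scaffolds, ~25 genes / 100 kb), a stable
#' outcrossing population of N = 100 (sample 20), and a collapsed
#' population that declines in two stages (60 generations at N = 20, then
#' 12 generations at N = 6 with selfing rate 0.25; sample 6, the size of
#' the relict stand the collapse emulates), mirroring a protracted decline
#' ending in a tiny kin-mating remnant. Mutation,
#' recombination and selection are jointly diversity-rescaled for the
#' desk-scale N: mu = 2.5e-6 and r = 2e-6 per bp so that 4*N*mu = 1e-3
#' matches the per-site diversity scale of the real species, and selection
#' coefficients scaled by the same factor so the selection-to-drift ratios
#' N*s stay in the regimes the real system has (tolerated missense
#' effectively neutral; deleterious missense selected at the stable N but
#' drifting during the collapse; loss-of-function recessives exposed and
#' purged by selection even at the collapse N). Dominance is unchanged.
#'
#' @param seed integer seed for the paired run.
#' @return A list with `template`, `stable`, `collapsed`, `mutmodel` and
#'   `recomb_rate`, ready for [simulate_two_populations()].
#' @export
study_conditions <- function(seed = 1L) {
  list(template = genome_template(n_scaffolds = 4L,
                                  scaffold_length = 500000L,
                                  gene_density = 25),
       stable = demography_config(list(c(72L, 100L)), selfing_rate = 0,
                                  sample_size = 20L, seed = seed),
       collapsed = demography_config(list(c(60L, 20L), c(12L, 6L)),
                                     selfing_rate = 0.25, sample_size = 6L,
                                     seed = seed),
       mutmodel = mutation_model(mu = 2.5e-6,
                                 selection = c(SYN = 0, TOL = -1e-3,
                                               DEL = -0.05, LOF = -0.8)),
       recomb_rate = 2e-6)
}
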
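#' Simulate a stable and a collapsed population over a shared genome
#'
#' Forward-in-time diploid Wright-Fisher simulation with multiplicative
#' selection, dominance, partial selfing and uniform recombination on an
#' infinite-sites grid. Both populations share a genome instance and a
#' neutral-equilibrium burn-in of `burn_in` generations (default 10N at the
#' ancestral size), then evolve independently under their own epoch
#' schedules — the split of two descendant populations from a common
#' ancestor. Present-day samples are drawn and packaged as datasets with
#' phased genotypes, simulated GQ/DP, three monomorphic ancestral-state
#' outgroup samples, and a truth table.
#'
#' Records in each dataset are the sites carrying at least one derived
#' allele in that population's sample (segregating or fixed-derived relative
#' to the reference, which is the ancestral founder sequence).
#'
#' @param template a [genome_template()].
#' @param stable,collapsed [demography_config()]s. Both run after the shared
#'   burn-in; name them by their role in the contrast.
#' @param mutmodel a [mutation_model()].
#' @param recomb_rate per-bp per-generation crossover rate.
#' @param burn_in burn-in generations at the stable config's first-epoch N
#'   (default 10 times that N).
#' @param outgroup_mismatch fraction of sites at which one random outgroup
#'   sample is flipped to the homozygous derived state, exercising the
#'   discordant-outgroup exclusion path (0 gives noise-free outgroups).
#' @param low_gq_fraction fraction of genotypes given GQ < 10 (rest GQ 99).
#' @param mean_dp Poisson mean of simulated per-genotype depth.
#' @param seed integer seed; defaults to the stable config's seed.
#' @return A list with elements `stable` and `collapsed`, each a
#'   `simulated_dataset`: `reference`, `genes`, `gm` (phased
#'   [genotype_matrix()]), `outgroups` (3-sample genotype matrix), `truth`
#'   (data.frame: scaffold, pos, ref, alt, ancestral, class, s, h,
#'   origin_gen, fixed), and `population`.
#' @export
simulate_two_populations <- function(template, stable, collapsed, mutmodel,
                                     recomb_rate = 1e-8, burn_in = NULL,
                                     outgroup_mismatch = 0.02,
                                     low_gq_fraction = 0.05, mean_dp = 20,
                                     seed = stable$seed) {
  stopifnot(inherits(template, "genome_template"),
            inherits(stable, "demography_config"),
            inherits(collapsed, "demography_config"),
            inherits(mutmodel, "mutation_model"))
  if (is.null(seed)) stop("a seed is required (stable$seed or `seed`)")
  set.seed(as.integer(seed))
  genome <- generate_genome(template)
  # coding-effect mutations target amino-acid-changing (conventional
  # zero-fold) sites of the reference CDS
  pool <- integer(0)
  if (nrow(genome$genes) > 0) {
    dmap <- classify_degeneracy(genome$reference, genome$genes,
                                rule = "conventional")
    zf <- dmap[dmap$label == "zero_fold", , drop = FALSE]
    sc_idx <- match(zf$scaffold, scaffold_names(template))
    pool <- (sc_idx - 1L) * template$scaffold_length + zf$pos - 1L
  }
  N0 <- stable$epochs$N[1]
  if (is.null(burn_in)) burn_in <- 10L * N0
  state0 <- list(H = matrix(raw(0), 2L * N0, 0L),
                 pos = integer(0), cls = integer(0), s = numeric(0),
                 h = numeric(0), alt = integer(0), origin = integer(0),
                 gen = 0L,
                 fixed = empty_fixed())
  state_anc <- if (burn_in > 0)
    run_epochs(state0, rep(N0, burn_in), rep(0, burn_in), template,
               mutmodel, recomb_rate, pool)
  else state0
  run_sched <- function(state, cfg) {
    nv <- rep(cfg$epochs$N, cfg$epochs$duration)
    sv <- rep(cfg$selfing_rate, length(nv))
    run_epochs(state, nv, sv, template, mutmodel, recomb_rate, pool)
  }
  st_s <- run_sched(state_anc, stable)
  st_c <- run_sched(state_anc, collapsed)
  ds_s <- build_dataset(st_s, stable, template, genome, mutmodel,
                        outgroup_mismatch, low_gq_fraction, mean_dp,
                        "stable")
  ds_c <- build_dataset(st_c, collapsed, template, genome, mutmodel,
                        outgroup_mismatch, low_gq_fraction, mean_dp,
                        "collapsed")
  list(stable = ds_s, collapsed = ds_c)
}

empty_fixed <- function() {
  data.frame(pos = integer(0), cls = integer(0), s = numeric(0),
             h = numeric(0), alt = integer(0), origin = integer(0),
             gen_fixed = integer(0))
}

run_epochs <- function(state, n_sched, selfing_sched, template, mutmodel,
                       recomb_rate, pool) {
  res <- .wf_run(state$H, state$pos, state$cls, state$s, state$h,
                 state$alt, state$origin, state$fixed$pos,
                 as.integer(n_sched), as.numeric(selfing_sched),
                 mutmodel$mu, recomb_rate,
                 template$n_scaffolds, template$scaffold_length,
                 as.numeric(mutmodel$class_fractions),
                 as.numeric(mutmodel$selection),
                 as.numeric(mutmodel$dominance),
                 c(FALSE, TRUE, TRUE, TRUE),
                 as.integer(pool), state$gen)
  fixed_new <- data.frame(pos = res$fixed_pos, cls = res$fixed_cls,
                          s = res$fixed_s, h = res$fixed_h,
                          alt = res$fixed_alt, origin = res$fixed_origin,
                          gen_fixed = res$fixed_gen)
  list(H = res$H, pos = res$pos, cls = res$cls, s = res$s, h = res$h,
       alt = res$alt, origin = res$origin, gen = res$gen,
       fixed = rbind(state$fixed, fixed_new))
}

# Assemble a present-day sample into a simulated_dataset.
build_dataset <- function(state, cfg, template, genome, mutmodel,
                          outgroup_mismatch, low_gq_fraction, mean_dp,
                          population) {
  N_fin <- nrow(state$H) / 2L
  n <- cfg$sample_size
  ind <- sort(sample.int(N_fin, n))
  hap_rows <- as.vector(rbind(2L * ind - 1L, 2L * ind))
  Hs <- matrix(as.integer(state$H[hap_rows, , drop = FALSE]), nrow = 2L * n)
  dcount <- colSums(Hs)
  keep <- which(dcount > 0L)  # derived allele present in the sample
  seg <- data.frame(pos = state$pos[keep], cls = state$cls[keep],
                    s = state$s[keep], h = state$h[keep],
                    alt = state$alt[keep], origin = state$origin[keep])
  a1_seg <- t(Hs[seq(1L, 2L * n, by = 2L), keep, drop = FALSE])
  a2_seg <- t(Hs[seq(2L, 2L * n, by = 2L), keep, drop = FALSE])
  fx <- state$fixed
  a1 <- rbind(a1_seg, matrix(1L, nrow(fx), n))
  a2 <- rbind(a2_seg, matrix(1L, nrow(fx), n))
  meta <- rbind(seg[c("pos", "cls", "s", "h", "alt", "origin")],
                fx[c("pos", "cls", "s", "h", "alt", "origin")])
  meta$fixed <- rep(c(FALSE, TRUE), c(nrow(seg), nrow(fx)))
  ord <- order(meta$pos)
  meta <- meta[ord, , drop = FALSE]
  a1 <- a1[ord, , drop = FALSE]
  a2 <- a2[ord, , drop = FALSE]
  # map global 0-based grid positions to scaffold coordinates and alleles
  L <- template$scaffold_length
  sc_idx <- meta$pos %/% L + 1L
  pos1 <- meta$pos %% L + 1L
  scafs <- scaffold_names(template)
  bases <- c("A", "C", "G", "T")
  ref <- character(nrow(meta))
  for (k in unique(sc_idx)) {
    sel <- sc_idx == k
    ref[sel] <- strsplit(as.character(
      Biostrings::extractAt(genome$reference[[k]],
                            IRanges::IRanges(pos1[sel], pos1[sel]))
    ), NULL) |> vapply(identity, character(1))
  }
  alt <- bases[(match(ref, bases) - 1L + meta$alt) %% 4L + 1L]
  samples <- sprintf("%s%02d", if (population == "collapsed") "Col" else "Stb",
                     seq_len(n))
  sites <- data.frame(scaffold = scafs[sc_idx], pos = pos1,
                      ref = ref, alt = alt)
  m <- nrow(sites)
  gq <- matrix(99L, m, n)
  nlow <- round(low_gq_fraction * length(gq))
  if (nlow > 0) {
    idx <- sample.int(length(gq), nlow)
    gq[idx] <- sample(0:9, nlow, replace = TRUE)
  }
  dp <- matrix(rpois(m * n, mean_dp), m, n)
  colnames(a1) <- colnames(a2) <- colnames(gq) <- colnames(dp) <- samples
  gm <- genotype_matrix(sites, a1, a2, gq = gq, dp = dp,
                        samples = samples, phased = TRUE)
  # outgroups: noise-free carriers of the ancestral (reference) state,
  # with an optional per-site disagreement flip of one outgroup
  og1 <- og2 <- matrix(0L, m, 3L)
  if (outgroup_mismatch > 0 && m > 0) {
    flip <- which(runif(m) < outgroup_mismatch)
    who <- sample.int(3L, length(flip), replace = TRUE)
    og1[cbind(flip, who)] <- 1L
    og2[cbind(flip, who)] <- 1L
  }
  og_samples <- paste0("Out", 1:3)
  colnames(og1) <- colnames(og2) <- og_samples
  outgroups <- genotype_matrix(sites, og1, og2,
                               gq = matrix(99L, m, 3L),
                               dp = matrix(as.integer(mean_dp), m, 3L),
                               samples = og_samples, phased = FALSE)
  truth <- data.frame(scaffold = sites$scaffold, pos = sites$pos,
                      ref = ref, alt = alt, ancestral = ref,
                      class = mutmodel$classes[meta$cls + 1L],
                      s = meta$s, h = meta$h, origin_gen = meta$origin,
                      fixed = meta$fixed)
  structure(list(reference = genome$reference, genes = genome$genes,
                 gm = gm, outgroups = outgroups, truth = truth,
                 population = population, template = template),
            class = "simulated_dataset")
}

#' @export
print.simulated_dataset <- function(x, ...) {
  cat(sprintf("simulated_dataset (%s): %d records, %d samples, %d fixed derived\n",
              x$population, n_sites(x$gm), n_samples(x$gm), sum(x$truth$fixed)))
  invisible(x)
}

#' Synthetic variant-effect predictor calls
#'
#' Emulates the call tables of three independent effect predictors run on
#' missense variants. Each predictor reports the truth-class verdict
#' (deleterious for DEL, benign for TOL) flipped independently with
#' probability `error_rate`, so the three-predictor intersection rule of
#' [assign_category()] is exercised with realistic disagreement. SYN and LOF
#' sites carry their annotation class and benign placeholders.
#'
#' @param truth truth table of a `simulated_dataset`.
#' @param error_rate per-predictor verdict flip probability.
#' @return data.frame with `scaffold`, `pos`, `annotation`
#'   (synonymous/missense/lof) and verdict columns `polyphen`, `provean`,
#'   `sift` ("del"/"benign").
#' @export
simulate_effect_calls <- function(truth, error_rate = 0.1) {
  annotation <- c(SYN = "synonymous", TOL = "missense", DEL = "missense",
                  LOF = "lof")[truth$class]
  verd <- matrix("benign", nrow(truth), 3L,
                 dimnames = list(NULL, c("polyphen", "provean", "sift")))
  mis <- annotation == "missense"
  for (j in 1:3) {
    true_del <- truth$class == "DEL"
    flip <- runif(nrow(truth)) < error_rate
    v <- ifelse(xor(true_del, flip), "del", "benign")
    verd[mis, j] <- v[mis]
  }
  data.frame(scaffold = truth$scaffold, pos = truth$pos,
             annotation = unname(annotation),
             polyphen = verd[, 1], provean = verd[, 2], sift = verd[, 3])
}
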
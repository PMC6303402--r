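# Replicate batteries shared across test files. Each battery is computed
# once per test session and cached; seeds are fixed so the whole suite is
# reproducible.

.battery_cache <- new.env(parent = emptyenv())

battery_cached <- function(key, compute) {
  if (is.null(.battery_cache[[key]])) .battery_cache[[key]] <- compute()
  .battery_cache[[key]]
}

# Full analysis of one simulated dataset along the package's standard path:
# QC cascade -> diversity / ROH / LD / load statistics.
analyse_for_battery <- function(d, lens) {
  cfgq <- filter_config(population_assignment = setNames(
    rep(d$population, n_samples(d$gm)), d$gm$samples))
  gm <- apply_cascade(erosionkit:::as_variant_set(d$gm), cfgq)$gm
  og <- gm_subset_sites(d$outgroups, match(site_key(gm), site_key(d$outgroups)))
  pol <- polarize(gm, og)
  eff <- assign_category(simulate_effect_calls(d$truth, 0.1))
  loads <- count_load(gm, pol, eff)
  sfsc <- sfs_by_category(gm, pol, eff)
  ac_alt <- rowSums(gm$a1 == 1L, na.rm = TRUE) + rowSums(gm$a2 == 1L, na.rm = TRUE)
  ac_n <- rowSums(!is.na(gm$a1)) + rowSums(!is.na(gm$a2))
  ld <- ld_decay(gm, max_dist = 250000L, bin_width = 10000L, max_pairs = 2e5)
  list(het = mean(colSums(geno_is_het(gm), na.rm = TRUE)) / sum(lens),
       froh = mean(froh_all(gm, sum(lens))$froh),
       ld_half_max = ld$half_max_distance,
       tajimas_d = tajimas_d(gm),
       hom_lof = mean(loads$n_hom_derived[loads$category == "LOF"]),
       lof_alleles_per_hap =
         sum(loads$derived_allele_count[loads$category == "LOF"]) /
           (2 * n_samples(gm)),
       fixed_del = count_fixed_derived(gm, pol, eff, "DEL"),
       n_segregating = sum(ac_alt > 0 & ac_alt < ac_n),
       sfs_syn = sfsc$SYN$counts, sfs_del = sfsc$DEL$counts)
}

# 50 paired collapsed-vs-stable replicates under the frozen study conditions.
directional_battery <- function(n_pairs = 50L, seed_base = 1000L) {
  battery_cached(sprintf("dir_%d_%d", n_pairs, seed_base), function() {
    lapply(seq_len(n_pairs), function(i) {
      seed <- seed_base + i
      sc <- study_conditions(seed)
      ds <- simulate_two_populations(sc$template, sc$stable, sc$collapsed,
                                     sc$mutmodel,
                                     recomb_rate = sc$recomb_rate,
                                     seed = seed)
      lens <- setNames(Biostrings::width(ds$stable$reference),
                       names(ds$stable$reference))
      list(stable = analyse_for_battery(ds$stable, lens),
           collapsed = analyse_for_battery(ds$collapsed, lens))
    })
  })
}

battery_wins <- function(batt, metric, direction = c("lower", "higher")) {
  direction <- match.arg(direction)
  s <- vapply(batt, function(p) p$stable[[metric]], numeric(1))
  cc <- vapply(batt, function(p) p$collapsed[[metric]], numeric(1))
  ok <- !is.na(s) & !is.na(cc)
  if (direction == "lower") mean(cc[ok] < s[ok]) else mean(cc[ok] > s[ok])
}

# 50 all-neutral equilibrium replicates at the real per-generation mutation
# rate on a scaled (4 Mb) genome; recombination at the scaled rate so that
# segregating sites are effectively unlinked and pooled-SFS tests are valid.
neutral_battery <- function(n_reps = 50L, seed_base = 3000L) {
  battery_cached(sprintf("neut_%d_%d", n_reps, seed_base), function() {
    lapply(seq_len(n_reps), function(i) {
      seed <- seed_base + i
      set.seed(seed)
      tpl <- genome_template(8L, 500000L, gene_density = 1)
      mm <- mutation_model(mu = 2.182e-8,
                           class_fractions = c(SYN = 1, TOL = 0, DEL = 0,
                                               LOF = 0))
      cfg <- demography_config(list(c(1000L, 100L)), 0, 20L, seed = seed)
      ds <- simulate_two_populations(tpl, cfg, cfg, mm, recomb_rate = 2e-6,
                                     outgroup_mismatch = 0, seed = seed)
      gm <- ds$stable$gm
      lens <- setNames(Biostrings::width(ds$stable$reference),
                       names(ds$stable$reference))
      w <- windowed_pi(gm, 50000L, 50000L, lens)
      list(pi = sum(w$pi * w$n_accessible_bp) / sum(w$n_accessible_bp),
           tajimas_d = tajimas_d(gm),
           sfs = site_frequency_spectrum(
             gm, ancestral = ds$stable$truth$ancestral)$counts)
    })
  })
}

# Instantaneous 25-fold crash, sampled shortly after; Tajima's D per rep.
crash_battery <- function(n_reps = 30L, seed_base = 7000L) {
  battery_cached(sprintf("crash_%d_%d", n_reps, seed_base), function() {
    vapply(seq_len(n_reps), function(i) {
      seed <- seed_base + i
      set.seed(seed)
      tpl <- genome_template(2L, 500000L, gene_density = 0)
      mm <- mutation_model(mu = 2.5e-6,
                           class_fractions = c(SYN = 1, TOL = 0, DEL = 0,
                                               LOF = 0))
      stable <- demography_config(list(c(8L, 100L)), 0, 20L, seed = seed)
      crashed <- demography_config(list(c(8L, 4L)), 0, 4L, seed = seed)
      ds <- simulate_two_populations(tpl, stable, crashed, mm,
                                     recomb_rate = 2e-6,
                                     outgroup_mismatch = 0, seed = seed)
      tajimas_d(ds$collapsed$gm)
    }, numeric(1))
  })
}

# Purifying selection strong (N = 100) vs relaxed by a sustained bottleneck
# (N = 16 at its own equilibrium); population-pooled zero:four-fold ratio.
# A 1 Mb genome is enough for this coding-site contrast.
z4_battery <- function(n_reps = 50L, seed_base = 5000L) {
  battery_cached(sprintf("z4_%d_%d", n_reps, seed_base), function() {
    lapply(seq_len(n_reps), function(i) {
      seed <- seed_base + i
      sc <- study_conditions(seed)
      tpl <- genome_template(2L, 500000L, gene_density = 25)
      stable <- demography_config(list(c(160L, 100L)), 0, 20L, seed = seed)
      relaxed <- demography_config(list(c(160L, 16L)), 0, 12L, seed = seed)
      ds <- simulate_two_populations(tpl, stable, relaxed,
                                     sc$mutmodel,
                                     recomb_rate = sc$recomb_rate,
                                     seed = seed)
      dmap <- classify_degeneracy(ds$stable$reference, ds$stable$genes)
      pooled_ratio <- function(gm) {
        z4 <- zero_four_ratio(gm, dmap)
        hz <- sum(z4$het_zero); hf <- sum(z4$het_four)
        nz <- sum(z4$n_zero); nf <- sum(z4$n_four)
        if (hf == 0) return(NA_real_)
        (hz / nz) / (hf / nf)
      }
      c(strong = pooled_ratio(ds$stable$gm),
        relaxed = pooled_ratio(ds$collapsed$gm))
    })
  })
}
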
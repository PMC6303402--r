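#' Default pipeline configuration
#'
#' A single flat configuration drives the whole simulate -> QC -> analysis
#' pipeline; every filtering and analysis threshold is a named key with the
#' study's canonical value as default (GQ 10, 1/3-3x depth, 5 bp indel pad,
#' 2 missing per population, HWE P < 0.001, 50 kb/10 kb windows, 10 kb
#' intergenic buffer, 100 kb ROH floor). Simulation keys default to
#' [study_conditions()].
#'
#' @param seed integer seed propagated to every stochastic stage.
#' @param outdir output directory.
#' @return A nested list of class `run_config`.
#' @export
default_run_config <- function(seed = 1L, outdir = tempfile("erosionrun")) {
  structure(list(
    seed = as.integer(seed),
    outdir = outdir,
    simulation = list(n_scaffolds = 4L, scaffold_length = 500000L,
                      gene_density = 25, mu = 2.5e-6, recomb_rate = 2e-6,
                      selection = c(SYN = 0, TOL = -1e-3, DEL = -0.05,
                                    LOF = -0.8),
                      stable_epochs = list(c(72L, 100L)),
                      collapsed_epochs = list(c(60L, 20L), c(12L, 6L)),
                      stable_selfing = 0, collapsed_selfing = 0.25,
                      stable_sample = 20L, collapsed_sample = 6L,
                      outgroup_mismatch = 0.02, low_gq_fraction = 0.05,
                      mean_dp = 20),
    qc = list(min_gq = 10L, depth_low_factor = 1 / 3, depth_high_factor = 3,
              indel_pad_bp = 5L, max_missing_per_population = 2L,
              hwe_alpha = 0.001),
    diversity = list(window = 50000L, step = 10000L,
                     intergenic_buffer = 10000L),
    roh = list(min_segment = 100000L, window_sites = 50L, max_het = 1L,
               min_snv = 25L),
    ld = list(max_dist = 250000L, bin_width = 10000L, max_pairs = 500000),
    load = list(predictor_error_rate = 0.1, outgroup_k = 3L)),
    class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Missing keys fall back to [default_run_config()] values.
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  usr <- yaml::read_yaml(path)
  cfg <- default_run_config()
  for (k in names(usr)) {
    if (is.list(usr[[k]]) && is.list(cfg[[k]])) {
      for (k2 in names(usr[[k]])) cfg[[k]][[k2]] <- usr[[k]][[k2]]
    } else cfg[[k]] <- usr[[k]]
  }
  cfg
}

#' Validate a pipeline configuration
#'
#' Collects every schema violation at once; an empty character vector means
#' the configuration is runnable. No stage is executed.
#'
#' @param config a `run_config` list.
#' @return Character vector of diagnostics.
#' @export
validate_config <- function(config) {
  d <- character(0)
  say <- function(...) d <<- c(d, sprintf(...))
  if (is.null(config$seed) || is.na(suppressWarnings(as.integer(config$seed))))
    say("seed: missing or not an integer")
  if (is.null(config$outdir)) say("outdir: missing")
  sim <- config$simulation
  if (is.null(sim)) {
    say("simulation: block missing (this pipeline runs on simulated data)")
  } else {
    for (side in c("stable", "collapsed")) {
      ep <- sim[[paste0(side, "_epochs")]]
      if (is.null(ep) || length(ep) == 0) {
        say("simulation: %s_epochs empty", side)
      } else {
        Ns <- vapply(ep, function(e) e[2], numeric(1))
        if (any(Ns < 2)) say("simulation: %s_epochs has diploid_N < 2", side)
        if (any(vapply(ep, function(e) e[1], numeric(1)) < 1))
          say("simulation: %s_epochs has duration < 1", side)
        ss <- sim[[paste0(side, "_sample")]]
        if (!is.null(ss) && length(Ns) && ss > Ns[length(Ns)])
          say("simulation: %s_sample exceeds final diploid_N", side)
      }
      sr <- sim[[paste0(side, "_selfing")]]
      if (!is.null(sr) && (sr < 0 || sr > 1))
        say("simulation: %s_selfing outside [0, 1]", side)
    }
    if (!is.null(sim$mu) && sim$mu <= 0) say("simulation: mu must be > 0")
  }
  qc <- config$qc
  if (!is.null(qc)) {
    if (!is.null(qc$depth_low_factor) && !is.null(qc$depth_high_factor) &&
        !(qc$depth_low_factor > 0 && qc$depth_low_factor < 1 &&
          qc$depth_high_factor > 1))
      say("qc: need 0 < depth_low_factor < 1 < depth_high_factor")
    if (!is.null(qc$indel_pad_bp) && qc$indel_pad_bp < 0)
      say("qc: indel_pad_bp negative")
    if (!is.null(qc$hwe_alpha) && (qc$hwe_alpha <= 0 || qc$hwe_alpha >= 1))
      say("qc: hwe_alpha outside (0, 1)")
  }
  dv <- config$diversity
  if (!is.null(dv) && !is.null(dv$window) && !is.null(dv$step) &&
      dv$window < dv$step)
    say("diversity: window smaller than step")
  ld <- config$ld
  if (!is.null(ld) && !is.null(ld$max_dist) && ld$max_dist <= 0)
    say("ld: max_dist must be positive")
  d
}

as_variant_set <- function(gm) {
  sites <- gm$sites
  sites$is_indel <- FALSE
  variant_set(sites, gm$a1, gm$a2, gq = gm$gq, dp = gm$dp,
              samples = gm$samples, phased = gm$phased)
}

#' Count sample-fixed derived variants in a category
#'
#' Number of polarized sites of the given category at which every called
#' genotype is homozygous derived — the sample-level fixed derived load.
#'
#' @inheritParams count_load
#' @param category one of "SYN", "TOL", "DEL", "LOF".
#' @return Integer count.
#' @export
count_fixed_derived <- function(gm, polarized, categories, category) {
  cat_idx <- match(site_key(gm), site_key(categories))
  sel <- polarized$status == "polarized" &
    !is.na(categories$category[cat_idx]) &
    categories$category[cat_idx] == category
  if (!any(sel)) return(0L)
  dos <- geno_dosage(gm)[sel, , drop = FALSE]
  flip <- polarized$ancestral[sel] != gm$sites$ref[sel]
  dos[flip, ] <- 2L - dos[flip, , drop = FALSE]
  called <- rowSums(!is.na(dos))
  sum(called > 0 & rowSums(dos == 2L, na.rm = TRUE) == called)
}

analyse_dataset <- function(ds, config, effects) {
  lens <- setNames(Biostrings::width(ds$reference), names(ds$reference))
  qc_cfg <- filter_config(
    min_gq = config$qc$min_gq,
    depth_low_factor = config$qc$depth_low_factor,
    depth_high_factor = config$qc$depth_high_factor,
    indel_pad_bp = config$qc$indel_pad_bp,
    max_missing_per_population = config$qc$max_missing_per_population,
    hwe_alpha = config$qc$hwe_alpha,
    population_assignment = setNames(rep(ds$population,
                                         n_samples(ds$gm)),
                                     ds$gm$samples))
  qc <- apply_cascade(as_variant_set(ds$gm), qc_cfg)
  gm <- qc$gm
  regions <- region_class_map(ds$genes, lens,
                              buffer = config$diversity$intergenic_buffer)
  win <- windowed_pi(gm, config$diversity$window, config$diversity$step,
                     scaffold_lengths = lens)
  het <- heterozygosity_by_region(gm, regions)
  taj <- tajimas_d(gm)
  rel <- if (n_samples(gm) >= 2) pairwise_relatedness(gm) else NULL
  dmap <- classify_degeneracy(ds$reference, ds$genes)
  z4 <- zero_four_ratio(gm, dmap)
  fr <- froh_all(gm, effective_length = sum(lens),
                 min_segment = config$roh$min_segment,
                 window_sites = config$roh$window_sites,
                 max_het = config$roh$max_het,
                 min_snv = config$roh$min_snv)
  ld <- ld_decay(gm, max_dist = config$ld$max_dist,
                 bin_width = config$ld$bin_width,
                 max_pairs = config$ld$max_pairs)
  og_idx <- match(site_key(gm), site_key(ds$outgroups))
  og <- gm_subset_sites(ds$outgroups, og_idx)
  pol <- polarize(gm, og, k = config$load$outgroup_k)
  cats <- assign_category(effects)
  loads <- count_load(gm, pol, cats, genes = ds$genes)
  sfs_cat <- sfs_by_category(gm, pol, cats)
  list(population = ds$population, qc_report = qc$report, gm = gm,
       windows = win, heterozygosity = het, tajimas_d = taj,
       relatedness = rel, zero_four = z4, froh = fr, ld = ld,
       polarized = pol, categories = cats, load = loads,
       sfs_by_category = sfs_cat,
       fixed_del = count_fixed_derived(gm, pol, cats, "DEL"),
       sfs = site_frequency_spectrum(
         gm_subset_sites(gm, pol$status == "polarized"),
         ancestral = pol$ancestral[pol$status == "polarized"]))
}

#' Run the full two-population pipeline
#'
#' Simulates the stable/collapsed pair, applies the QC cascade, and computes
#' every diversity, degeneracy, ROH, LD and load statistic per population
#' plus a between-population comparison block. All tables are written under
#' `config$outdir` and the aggregated report is returned (and written as
#' JSON). Stage failures abort with the stage name; outputs of completed
#' stages are retained.
#'
#' @param config a `run_config` (see [default_run_config()] /
#'   [read_run_config()]).
#' @return The report, invisibly: a list with per-population metric blocks
#'   and a `comparison` block.
#' @export
run_all <- function(config) {
  diag <- validate_config(config)
  if (length(diag))
    stop("invalid configuration:\n  ", paste(diag, collapse = "\n  "))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  set.seed(as.integer(config$seed))
  sim <- config$simulation
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  ds <- stage("simulate", {
    template <- genome_template(sim$n_scaffolds, sim$scaffold_length,
                                sim$gene_density)
    stable <- demography_config(sim$stable_epochs, sim$stable_selfing,
                                sim$stable_sample, seed = config$seed)
    collapsed <- demography_config(sim$collapsed_epochs,
                                   sim$collapsed_selfing,
                                   sim$collapsed_sample, seed = config$seed)
    mm <- if (is.null(sim$selection)) mutation_model(mu = sim$mu) else
      mutation_model(mu = sim$mu, selection = unlist(sim$selection))
    simulate_two_populations(template, stable, collapsed, mm,
                             recomb_rate = sim$recomb_rate,
                             outgroup_mismatch = sim$outgroup_mismatch,
                             low_gq_fraction = sim$low_gq_fraction,
                             mean_dp = sim$mean_dp, seed = config$seed)
  })
  effects <- lapply(ds, function(d)
    simulate_effect_calls(d$truth, config$load$predictor_error_rate))
  res <- list()
  for (side in names(ds))
    res[[side]] <- stage(paste0("analyse_", side),
                         analyse_dataset(ds[[side]], config,
                                         effects[[side]]))
  comparison <- stage("compare", {
    loads <- rbind(res$stable$load, res$collapsed$load)
    grouping <- c(setNames(rep("stable", n_samples(res$stable$gm)),
                           res$stable$gm$samples),
                  setNames(rep("collapsed", n_samples(res$collapsed$gm)),
                           res$collapsed$gm$samples))
    mw <- compare_populations(loads, grouping)
    mean_het <- function(r) mean(
      r$heterozygosity[r$heterozygosity >= 0 & r$region == "genome"],
      na.rm = TRUE)
    hom_lof <- function(r) mean(
      r$load$n_hom_derived[r$load$category == "LOF"])
    summary <- data.frame(
      metric = c("mean_pi", "mean_heterozygosity", "tajimas_d",
                 "mean_froh", "ld_half_max_bp", "mean_hom_derived_lof",
                 "n_fixed_del"),
      stable = c(mean(res$stable$windows$pi),
                 mean_het(res$stable$heterozygosity),
                 res$stable$tajimas_d, mean(res$stable$froh$froh),
                 res$stable$ld$half_max_distance, hom_lof(res$stable),
                 res$stable$fixed_del),
      collapsed = c(mean(res$collapsed$windows$pi),
                    mean_het(res$collapsed$heterozygosity),
                    res$collapsed$tajimas_d, mean(res$collapsed$froh$froh),
                    res$collapsed$ld$half_max_distance, hom_lof(res$collapsed),
                    res$collapsed$fixed_del))
    dir_expect <- c(-1, -1, 1, 1, 1, -1, 1)  # collapsed vs stable
    summary$collapsed_vs_stable <- ifelse(
      is.na(summary$collapsed) | is.na(summary$stable), NA,
      ifelse(summary$collapsed > summary$stable, "higher",
             ifelse(summary$collapsed < summary$stable, "lower", "equal")))
    summary$as_expected <- ifelse(is.na(summary$collapsed_vs_stable), NA,
      (summary$collapsed_vs_stable == "higher") == (dir_expect > 0) &
        summary$collapsed_vs_stable != "equal")
    list(mann_whitney = mw, summary = summary)
  })
  stage("write", {
    wt <- function(df, name) write.table(
      df, file.path(config$outdir, name), sep = "\t", quote = FALSE,
      row.names = FALSE)
    for (side in names(res)) {
      r <- res[[side]]
      wt(r$windows, sprintf("%s_windows.tsv", side))
      wt(r$heterozygosity, sprintf("%s_heterozygosity.tsv", side))
      wt(r$zero_four, sprintf("%s_zero_four_ratio.tsv", side))
      wt(r$froh, sprintf("%s_froh.tsv", side))
      wt(r$ld$curve, sprintf("%s_ld_curve.tsv", side))
      wt(r$load, sprintf("%s_load.tsv", side))
    }
    wt(comparison$mann_whitney, "comparison_mann_whitney.tsv")
    wt(comparison$summary, "comparison_summary.tsv")
  })
  report <- list(
    schema_version = "1.0",
    seed = as.integer(config$seed),
    populations = lapply(res, function(r) list(
      n_sites_qc = r$qc_report$n_surviving,
      qc_removed = as.list(r$qc_report$removed),
      mean_pi = mean(r$windows$pi),
      heterozygosity_by_region = stats::aggregate(
        heterozygosity ~ region, data = r$heterozygosity, FUN = mean),
      tajimas_d = r$tajimas_d,
      froh = setNames(r$froh$froh, r$froh$individual),
      ld_half_max = r$ld$half_max_distance,
      ld_max_r2 = r$ld$max_r2,
      zero_four_ratio = setNames(r$zero_four$ratio,
                                 r$zero_four$individual),
      mean_hom_derived_lof =
        mean(r$load$n_hom_derived[r$load$category == "LOF"]),
      n_fixed_del = r$fixed_del)),
    comparison = comparison)
  jsonlite::write_json(report, file.path(config$outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       force = TRUE)
  invisible(c(res, list(comparison = comparison, report = report)))
}
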
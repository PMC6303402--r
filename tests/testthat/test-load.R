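og_gm <- function(gm, g1, g2, g3) {
  m <- n_sites(gm)
  g1 <- rep(g1, length.out = m)
  g2 <- rep(g2, length.out = m)
  g3 <- rep(g3, length.out = m)
  a1 <- cbind(substr(g1, 1, 1), substr(g2, 1, 1), substr(g3, 1, 1))
  a2 <- cbind(substr(g1, 3, 3), substr(g2, 3, 3), substr(g3, 3, 3))
  mode(a1) <- mode(a2) <- "integer"
  colnames(a1) <- colnames(a2) <- paste0("Out", 1:3)
  genotype_matrix(gm$sites, a1, a2, samples = paste0("Out", 1:3))
}

test_that("polarization follows the three-outgroup homozygosity rule", {
  gm <- gm_from_strings(matrix("0/1", 5, 2), ref = "A", alt = "T")
  pol <- polarize(gm, og_gm(gm,
                            c("0/0", "1/1", "0/0", "0/1", "0/0"),
                            c("0/0", "1/1", "0/0", "0/0", "0/0"),
                            c("0/0", "1/1", "1/1", "0/0", "0/0")))
  expect_equal(pol$status,
               c("polarized", "polarized", "discordant_outgroups",
                 "discordant_outgroups", "polarized"))
  expect_equal(pol$ancestral[1:2], c("A", "T"))
  expect_equal(pol$derived[1:2], c("T", "A"))
  # outgroup count must match k
  expect_error(polarize(gm, gm_subset_samples(og_gm(gm, "0/0", "0/0", "0/0"),
                                              1:2)),
               "expected 3")
})

test_that("missing outgroup genotypes get their own exclusion code", {
  gm <- gm_from_strings(matrix("0/1", 1, 2))
  og <- og_gm(gm, "0/0", "0/0", "0/0")
  og$a1[1, 2] <- NA_integer_
  pol <- polarize(gm, og)
  expect_equal(pol$status, "missing_outgroups")
})

test_that("category assignment applies the three-predictor intersection", {
  eff <- data.frame(scaffold = "s", pos = 1:5,
                    annotation = c("missense", "missense", "synonymous",
                                   "lof", "missense"),
                    polyphen = c("del", "del", "del", "benign", "del"),
                    provean = c("del", "del", "benign", "benign", NA),
                    sift = c("del", "benign", "del", "benign", "del"))
  out <- assign_category(eff)
  expect_equal(out$category, c("DEL", "TOL", "SYN", "LOF", NA))
})

test_that("load counting applies the het-once hom-twice rule", {
  # 5 DEL sites for one individual: 3 het + 2 hom-derived -> count 7
  gm <- gm_from_strings(matrix(c("0/1", "0/1", "0/1", "1/1", "1/1",
                                 "0/0", "0/0", "0/0", "0/0", "0/0"), 5, 2),
                        ref = "A", alt = "T")
  pol <- data.frame(scaffold = gm$sites$scaffold, pos = gm$sites$pos,
                    status = "polarized", ancestral = "A", derived = "T")
  cats <- data.frame(scaffold = gm$sites$scaffold, pos = gm$sites$pos,
                     category = "DEL")
  load <- count_load(gm, pol, cats)
  s1 <- load[load$individual == "S1" & load$category == "DEL", ]
  expect_equal(s1$n_het, 3L)
  expect_equal(s1$n_hom_derived, 2L)
  expect_equal(s1$derived_allele_count, 7L)
  s2 <- load[load$individual == "S2" & load$category == "DEL", ]
  expect_equal(s2$derived_allele_count, 0L)
  expect_equal(s2$n_hom_ancestral, 5L)
  # ancestral = alt flips the derived dosage
  pol_flip <- transform(pol, ancestral = "T", derived = "A")
  load_flip <- count_load(gm, pol_flip, cats)
  s2f <- load_flip[load_flip$individual == "S2" &
                     load_flip$category == "DEL", ]
  expect_equal(s2f$n_hom_derived, 5L)
  expect_equal(s2f$derived_allele_count, 10L)
})

test_that("per-category tallies conserve the polarized site count", {
  ds <- tiny_pair(seed = 51L)
  d <- ds$stable
  og <- d$outgroups
  pol <- polarize(d$gm, og)
  eff <- assign_category(simulate_effect_calls(d$truth, 0.1))
  load <- count_load(d$gm, pol, eff)
  for (ind in unique(load$individual)) {
    li <- load[load$individual == ind, ]
    expect_equal(li$n_het + li$n_hom_derived + li$n_hom_ancestral +
                   li$n_missing, li$n_sites)
  }
  n_polarized_categorised <- sum(pol$status == "polarized" &
    !is.na(eff$category[match(site_key(d$gm), site_key(eff))]))
  expect_equal(sum(load$n_sites[load$individual == load$individual[1]]),
               n_polarized_categorised)
})

test_that("pipeline load counts equal the simulator truth exactly", {
  ds <- tiny_pair(seed = 52L, mismatch = 0)
  for (d in ds) {
    pol <- polarize(d$gm, d$outgroups)
    expect_true(all(pol$status == "polarized"))
    # categories directly from the truth classes (no predictor noise)
    cats <- data.frame(scaffold = d$truth$scaffold, pos = d$truth$pos,
                       category = d$truth$class)
    load <- count_load(d$gm, pol, cats)
    # independent oracle: count derived alleles from the genotype matrix
    dos <- geno_dosage(d$gm)
    for (cls in c("SYN", "TOL", "DEL", "LOF")) {
      sel <- d$truth$class == cls
      for (j in seq_along(d$gm$samples)) {
        expected <- sum(dos[sel, j])
        got <- load$derived_allele_count[
          load$individual == d$gm$samples[j] & load$category == cls]
        expect_identical(as.integer(expected), as.integer(got))
      }
    }
  }
})

# Independent Mann-Whitney oracle: U from pairwise comparisons, exact p by
# enumerating group assignments.
mw_oracle <- function(x, y) {
  U_of <- function(a, b) sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  v <- c(x, y)
  n1 <- length(x)
  mu <- n1 * length(y) / 2
  obs <- abs(U_of(x, y) - mu)
  idx <- combn(length(v), n1)
  us <- apply(idx, 2, function(i) U_of(v[i], v[-i]))
  list(U = U_of(x, y), p = mean(abs(us - mu) >= obs - 1e-9))
}

test_that("the Mann-Whitney test matches its stated example and oracle", {
  t1 <- mw_test(1:3, 4:6)
  expect_equal(t1$U, 0)
  expect_equal(t1$p_value, 0.1)
  # identical groups carry no signal
  expect_gte(mw_test(c(5, 5, 5, 5), c(5, 5, 5, 5))$p_value, 0.99)
  set.seed(77)
  for (rep in 1:40) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    x <- sample(1:5, n1, TRUE)   # ties likely
    y <- sample(1:5, n2, TRUE)
    got <- mw_test(x, y)
    want <- mw_oracle(x, y)
    expect_equal(got$U, want$U)
    expect_equal(got$p_value, want$p, tolerance = 1e-12)
  }
  # tie-free cases cross-checked against the stats package exact test
  for (rep in 1:20) {
    x <- sample(100, 5); y <- sample(200:300, 6)
    expect_equal(mw_test(x, y)$p_value,
                 wilcox.test(x, y, exact = TRUE)$p.value, tolerance = 1e-12)
  }
})

test_that("population comparison reports medians and two-sided p-values", {
  load <- rbind(
    data.frame(individual = paste0("a", 1:4), category = "DEL",
               n_sites = 10L, n_het = c(1L, 2L, 3L, 2L),
               n_hom_derived = c(5L, 6L, 7L, 6L), n_hom_ancestral = 1L,
               n_missing = 0L, derived_allele_count = c(11L, 14L, 17L, 14L)),
    data.frame(individual = paste0("b", 1:4), category = "DEL",
               n_sites = 10L, n_het = c(4L, 5L, 6L, 5L),
               n_hom_derived = c(1L, 2L, 1L, 2L), n_hom_ancestral = 4L,
               n_missing = 0L, derived_allele_count = c(6L, 9L, 8L, 9L)))
  grouping <- setNames(rep(c("A", "B"), each = 4), load$individual)
  cmp <- compare_populations(load, grouping)
  hom <- cmp[cmp$metric == "n_hom_derived", ]
  expect_equal(hom$median1, 6)
  expect_equal(hom$median2, 1.5)
  expect_lt(hom$p_value, 0.05)
  expect_error(compare_populations(load[c(1, 5:8), ], grouping),
               ">= 2 individuals")
})

test_that("per-category spectra partition the all-sites spectrum", {
  ds <- tiny_pair(seed = 53L)
  d <- ds$stable
  pol <- polarize(d$gm, d$outgroups)
  eff <- assign_category(simulate_effect_calls(d$truth, 0))
  sfs <- sfs_by_category(d$gm, pol, eff)
  per_cat <- Reduce(`+`, lapply(sfs[c("SYN", "TOL", "DEL", "LOF")],
                                `[[`, "counts"))
  expect_equal(per_cat, sfs$ALL$counts)
  # single DEL site at derived count 1
  gm1 <- gm_from_strings(matrix(c("0/1", "0/0"), 1, 2), ref = "A", alt = "T")
  pol1 <- data.frame(scaffold = gm1$sites$scaffold, pos = gm1$sites$pos,
                     status = "polarized", ancestral = "A", derived = "T")
  cat1 <- data.frame(scaffold = gm1$sites$scaffold, pos = gm1$sites$pos,
                     category = "DEL")
  sfs1 <- sfs_by_category(gm1, pol1, cat1)
  expect_equal(unname(sfs1$DEL$counts), c(1, 0, 0))
  expect_equal(sum(sfs1$SYN$counts), 0)
})

test_that("selection shifts deleterious spectra toward rare classes", {
  batt <- directional_battery()
  syn <- Reduce(`+`, lapply(batt, function(p) p$stable$sfs_syn))
  del <- Reduce(`+`, lapply(batt, function(p) p$stable$sfs_del))
  expect_gt(del[1] / sum(del), syn[1] / sum(syn))
})

test_that("collapse purges loss-of-function alleles at the allele level", {
  batt <- directional_battery()
  expect_gte(battery_wins(batt, "lof_alleles_per_hap", "lower"), 0.8)
})
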
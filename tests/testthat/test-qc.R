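# Independent oracle for the exact HWE test: direct log-factorial evaluation
# of the conditional law of heterozygote counts given allele counts.
hwe_oracle <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  na <- 2 * n_aa + n_ab
  nb <- 2 * n_bb + n_ab
  if (na == 0 || nb == 0) return(1)
  rare <- min(na, nb)
  hets <- seq(rare %% 2, rare, by = 2)
  lp <- vapply(hets, function(h) {
    lfactorial(n) - lfactorial((na - h) / 2) - lfactorial(h) -
      lfactorial((nb - h) / 2) + h * log(2)
  }, numeric(1))
  p <- exp(lp - max(lp))
  p <- p / sum(p)
  obs <- p[match(n_ab, hets)]
  sum(p[p <= obs * (1 + 1e-12)])
}

test_that("multiallelic records are removed and biallelic ones retained", {
  sites <- data.frame(scaffold = "s", pos = c(10L, 20L, 30L),
                      ref = "A", alt = c("C,T", "C", "G"))
  a <- matrix(0L, 3, 2, dimnames = list(NULL, c("x", "y")))
  vs <- variant_set(sites, a, a)
  out <- remove_multiallelic(vs)
  expect_equal(out$sites$pos, c(20L, 30L))
  # no multiallelic input -> identity
  out2 <- remove_multiallelic(out)
  expect_equal(out2$sites, out$sites)
})

test_that("SNVs at or within the pad of an indel are removed, boundary inclusive", {
  sites <- data.frame(scaffold = "s", pos = c(100L, 105L, 106L),
                      ref = c("A", "C", "G"), alt = c("AT", "T", "T"))
  a <- matrix(0L, 3, 2, dimnames = list(NULL, c("x", "y")))
  vs <- variant_set(sites, a, a)
  out <- mask_near_indels(vs, pad = 5L)
  expect_equal(out$sites$pos, 106L)   # 105 removed (inclusive), 106 kept
  expect_error(mask_near_indels(vs, pad = -1L), "non-negative")
})

test_that("a 10-SNV / 2-indel fixture matches the hand-applied proximity rule", {
  # indel spans: 100..101 (+5 -> 95..106) and 300..300 (+5 -> 295..305)
  snv_pos <- c(50L, 94L, 95L, 106L, 107L, 200L, 294L, 295L, 305L, 306L)
  sites <- data.frame(scaffold = "s",
                      pos = c(snv_pos, 100L, 300L),
                      ref = c(rep("A", 10), "AT", "G"),
                      alt = c(rep("T", 10), "A", "GC"))
  a <- matrix(0L, 12, 2, dimnames = list(NULL, c("x", "y")))
  vs <- variant_set(sites, a, a)
  out <- mask_near_indels(vs, pad = 5L)
  expect_equal(out$sites$pos, c(50L, 94L, 107L, 200L, 294L, 306L))
})

test_that("genotype-level filter masks exactly the GQ and depth failures", {
  # one sample, 10 sites, mean depth exactly 21 -> bounds (7, 63)
  dp <- c(6L, 7L, 63L, 64L, 10L, 10L, 10L, 10L, 10L, 20L)
  gq <- c(rep(99L, 8), 9L, 10L)
  sites <- data.frame(scaffold = "s", pos = seq(10L, 100L, 10L),
                      ref = "A", alt = "T")
  a <- matrix(0L, 10, 1, dimnames = list(NULL, "x"))
  vs <- vs_fixture(sites, a, a, matrix(gq, 10, 1), matrix(dp, 10, 1), "x")
  out <- genotype_level_filter(vs, filter_config())
  masked <- is.na(out$a1[, 1])
  expect_equal(which(masked), c(1L, 4L, 9L))  # DP 6 < 7, DP 64 > 63, GQ 9
  # all clean -> identity
  vs2 <- vs_fixture(sites, a, a, matrix(99L, 10, 1), matrix(20L, 10, 1), "x")
  out2 <- genotype_level_filter(vs2, filter_config())
  expect_false(anyNA(out2$a1))
})

test_that("missingness filter removes sites exceeding the per-population cap", {
  samples <- c(paste0("a", 1:4), paste0("b", 1:4))
  cfg <- filter_config(population_assignment = setNames(
    rep(c("A", "B"), each = 4), samples))
  a1 <- matrix(0L, 3, 8, dimnames = list(NULL, samples))
  a2 <- a1
  a1[1, 1:3] <- NA_integer_; a2[1, 1:3] <- NA_integer_  # 3 missing in A
  a1[2, c(1, 2, 5, 6)] <- NA_integer_                   # 2 and 2 missing
  a2[2, c(1, 2, 5, 6)] <- NA_integer_
  sites <- data.frame(scaffold = "s", pos = c(10L, 20L, 30L),
                      ref = "A", alt = "T")
  vs <- vs_fixture(sites, a1, a2, matrix(99L, 3, 8), matrix(20L, 3, 8),
                   samples)
  out <- missingness_filter(vs, cfg)
  expect_equal(out$sites$pos, c(20L, 30L))
  expect_error(missingness_filter(vs, filter_config()), "population_assignment")
})

test_that("the exact HWE test matches the spec examples and the enumeration oracle", {
  expect_equal(hwe_exact_test(10, 0, 0), 1.0)          # monomorphic
  expect_equal(hwe_exact_test(5, 0, 5), hwe_oracle(5, 0, 5), tolerance = 1e-12)
  # all-het extreme: small p for large n, equal allele counts
  expect_lt(hwe_exact_test(0, 40, 0), 1e-6)
  expect_lt(hwe_exact_test(0, 13, 0), 0.001)
  expect_gt(hwe_exact_test(0, 4, 0), 0.05)
  # exhaustive check at moderate n against the independent oracle
  for (n in c(2:12)) {
    for (na in 0:n) {
      rare <- min(na, 2 * n - na)
      for (h in seq(rare %% 2, rare, by = 2)) {
        naa <- (na - h) / 2
        nbb <- n - naa - h
        expect_equal(hwe_exact_test(naa, h, nbb), hwe_oracle(naa, h, nbb),
                     tolerance = 1e-12)
      }
    }
  }
})


test_that("the cascade removes one site per rule and the report balances", {
  fx <- cascade_fixture()
  res <- apply_cascade(fx$vs, fx$cfg)
  expect_equal(res$report$n_input, 21L)
  expect_equal(res$report$n_surviving, 15L)
  expect_equal(res$report$removed,
               c(multiallelic = 1L, indel_record = 1L, near_indel = 1L,
                 genotype_level_site = 1L, missingness = 1L, hwe = 1L))
  expect_equal(res$report$n_input,
               res$report$n_surviving + sum(res$report$removed))
  # the surviving sites are exactly the benign ones
  expect_false(any(res$gm$sites$pos %in% c(100L, 103L, 17000L, 16000L,
                                           20000L, 21000L)))
})

test_that("an all-passing input passes unchanged with a zero report", {
  fx <- cascade_fixture()
  res <- apply_cascade(erosionkit:::vs_subset_sites(fx$vs, 1:15), fx$cfg)
  expect_equal(res$report$n_surviving, 15L)
  expect_true(all(res$report$removed == 0L))
  expect_equal(res$report$genotypes_masked, 0L)
})

test_that("HWE removal respects the alpha threshold on either side", {
  # all-het site with 13 individuals has exact p ~ 7.9e-4
  p <- hwe_exact_test(0, 13, 0)
  expect_lt(p, 0.001)
  samples <- sprintf("a%02d", 1:13)
  cfg_above <- filter_config(hwe_alpha = p * 1.01,
                             population_assignment = setNames(
                               rep("A", 13), samples))
  cfg_below <- filter_config(hwe_alpha = p * 0.99,
                             population_assignment = setNames(
                               rep("A", 13), samples))
  a1 <- matrix(0L, 1, 13, dimnames = list(NULL, samples))
  a2 <- matrix(1L, 1, 13, dimnames = list(NULL, samples))
  vs <- vs_fixture(data.frame(scaffold = "s", pos = 10L, ref = "A",
                              alt = "T"),
                   a1, a2, matrix(99L, 1, 13), matrix(20L, 1, 13), samples)
  expect_equal(apply_cascade(vs, cfg_above)$report$removed[["hwe"]], 1L)
  expect_equal(apply_cascade(vs, cfg_below)$report$removed[["hwe"]], 0L)
})

test_that("the cascade is idempotent", {
  fx <- cascade_fixture()
  once <- apply_cascade(fx$vs, fx$cfg)
  twice <- apply_cascade(erosionkit:::as_variant_set(once$gm), fx$cfg)
  expect_equal(twice$gm$sites, once$gm$sites)
  expect_identical(twice$gm$a1, once$gm$a1)
  expect_true(all(twice$report$removed == 0L))
})
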
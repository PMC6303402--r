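# Brute-force oracle: mean pairwise haplotype difference per site, summed
# over sites, divided by the accessible length.
pi_bruteforce <- function(hap, accessible) {
  n <- nrow(hap)
  tot <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- !is.na(hap[i, ]) & !is.na(hap[j, ])
      if (!any(ok)) next
      # per-site average over available pairs
      for (s in which(ok)) {
        nm <- sum(!is.na(hap[, s]))
        tot <- tot + (hap[i, s] != hap[j, s]) / choose(nm, 2)
      }
    }
  }
  tot / accessible
}

test_that("windowed pi matches its definition on elementary cases", {
  # one diploid, heterozygous at 1 of 100 accessible bp -> pi = 0.01
  gm <- gm_from_strings(matrix("0|1", 1, 1), pos = 50L)
  w <- windowed_pi(gm, window = 100L, step = 100L,
                   scaffold_lengths = c(scaf_1 = 100L))
  expect_equal(w$pi, 0.01)
  # monomorphic window -> 0
  gm0 <- gm_from_strings(matrix(c("1/1", "1/1"), 1, 2), pos = 50L)
  w0 <- windowed_pi(gm0, 100L, 100L, c(scaf_1 = 100L))
  expect_equal(w0$pi, 0)
  expect_error(windowed_pi(gm, window = 10L, step = 100L), "window")
  expect_equal(nrow(windowed_pi(gm_from_strings(
    matrix(character(0), 0, 2)), 100L, 100L)), 0L)
})

test_that("windowed pi equals the brute-force pairwise oracle on fuzz cases", {
  set.seed(42)
  for (case in 1:1000) {
    hap <- matrix(sample(c(0L, 1L), 30, replace = TRUE), 6, 5)
    if (case %% 3 == 0) hap[sample(30, 3)] <- NA_integer_
    gm <- gm_from_haplotypes(hap, pos = sort(sample(1000L, 5L)))
    w <- windowed_pi(gm, 1000L, 1000L, c(scaf_1 = 1000L))
    expect_equal(w$pi, pi_bruteforce(hap, 1000L), tolerance = 1e-12)
  }
})

test_that("region classes partition the genome and respect the buffer", {
  genes <- data.frame(gene_id = c("g1", "g1", "g2"),
                      scaffold = "sc",
                      start = c(30000L, 31000L, 80000L),
                      end = c(30500L, 31600L, 80900L),
                      strand = c("+", "+", "-"),
                      phase = 0L, exon_rank = c(1L, 2L, 1L))
  map <- region_class_map(genes, c(sc = 120000L), buffer = 10000L)
  lens <- region_class_lengths(map)
  expect_equal(sum(lens), 120000)
  # intron = the gap inside g1's span
  expect_equal(unname(lens["intron"]), 31000 - 30500 - 1)
  # every intergenic base is >= 10 kb from any coding base
  inter <- map[map$class == "intergenic", ]
  cds <- map[map$class == "coding", ]
  for (i in seq_len(nrow(inter))) {
    d <- pmax(cds$start - inter$end[i], inter$start[i] - cds$end)
    expect_true(all(d > 10000L))
  }
  expect_equal(region_lookup(map, "sc", c(30100L, 30700L, 35000L, 60000L)),
               c("coding", "intron", "near_gene", "intergenic"))
})

test_that("heterozygosity by region counts hets over accessible class length", {
  genes <- data.frame(gene_id = "g1", scaffold = "sc", start = 1001L,
                      end = 2000L, strand = "+", phase = 0L, exon_rank = 1L)
  map <- region_class_map(genes, c(sc = 60000L), buffer = 10000L)
  # 3 heterozygous coding sites for S1; S2 fully homozygous
  gm <- gm_from_strings(matrix(c("0/1", "0/0", "0/1", "0/0", "0/1", "0/0"),
                               3, 2, byrow = TRUE),
                        pos = c(1100L, 1200L, 1300L), scaffold = "sc")
  het <- heterozygosity_by_region(gm, map)
  s1_coding <- het[het$individual == "S1" & het$region == "coding", ]
  expect_equal(s1_coding$heterozygosity, 3 / 1000)
  s2 <- het[het$individual == "S2", ]
  expect_true(all(s2$heterozygosity == 0))
})

test_that("the SFS counts derived alleles and handles degenerate inputs", {
  # 1 derived allele among 2n = 8 -> bin 1
  gm <- gm_from_strings(matrix(c("0|1", "0|0", "0|0", "0|0"), 1, 4))
  sf <- site_frequency_spectrum(gm, ancestral = "A")
  expect_equal(unname(sf$counts), c(1, rep(0, 6)))
  # ancestral = alt flips the derived allele
  sf2 <- site_frequency_spectrum(gm, ancestral = "T")
  expect_equal(unname(sf2$counts), c(rep(0, 6), 1))
  # fixed-derived input is monomorphic in the sample -> empty SFS
  gmf <- gm_from_strings(matrix("1|1", 2, 4))
  sff <- site_frequency_spectrum(gmf, ancestral = c("A", "A"))
  expect_equal(sum(sff$counts), 0)
  expect_equal(sff$n_monomorphic, 2L)
  # ancestral allele matching neither ref nor alt -> excluded and counted
  sfx <- site_frequency_spectrum(gm, ancestral = "G")
  expect_equal(sfx$n_excluded_ancestral, 1L)
  expect_equal(sum(sfx$counts), 0)
})

test_that("hypergeometric projection preserves totals of polymorphic mass", {
  set.seed(7)
  hap <- matrix(rbinom(80, 1, 0.3), 8, 10)
  hap[1, 1:3] <- NA_integer_
  gm <- gm_from_haplotypes(hap, pos = seq(100L, 1000L, 100L))
  sf <- site_frequency_spectrum(gm, ancestral = rep("A", 10),
                                on_missing = "project", n_project = 6L)
  # projected counts are fractional but each fully-typed segregating site
  # contributes at most 1
  expect_lte(sum(sf$counts), 10)
  expect_equal(sf$n_hap, 6L)
})

test_that("Tajima's D equals a directly evaluated textbook formula", {
  set.seed(11)
  for (rep in 1:20) {
    nh <- sample(c(4L, 6L, 10L), 1)
    S <- sample(3:8, 1)
    hap <- matrix(0L, nh, S)
    for (s in seq_len(S)) hap[sample(nh, sample(nh - 1, 1)), s] <- 1L
    gm <- gm_from_haplotypes(hap, pos = seq_len(S) * 50L)
    # independent oracle, written out in full
    n <- nh
    seg <- apply(hap, 2, function(col) length(unique(col)) > 1)
    Sn <- sum(seg)
    k <- 0
    for (i in seq_len(n - 1)) for (j in (i + 1):n)
      k <- k + sum(hap[i, ] != hap[j, ])
    k <- k / choose(n, 2)
    a1 <- sum(1 / 1:(n - 1)); a2 <- sum(1 / (1:(n - 1))^2)
    b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
    c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
    e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
    D_oracle <- (k - Sn / a1) / sqrt(e1 * Sn + e2 * Sn * (Sn - 1))
    expect_equal(tajimas_d(gm), D_oracle, tolerance = 1e-12)
  }
})

test_that("Tajima's D is undefined without segregating sites or haplotypes", {
  gm <- gm_from_strings(matrix("0/0", 2, 4))
  expect_true(is.na(tajimas_d(gm)))
  gm2 <- gm_from_strings(matrix(c("0/1"), 1, 1))
  expect_true(is.na(tajimas_d(gm2)))
})

test_that("neutral equilibrium simulations give |mean D| < 0.2", {
  d <- vapply(neutral_battery(), `[[`, numeric(1), "tajimas_d")
  expect_lt(abs(mean(d, na.rm = TRUE)), 0.2)
})

test_that("KING-robust kinship recovers duplicates, parent-offspring and unrelated pairs", {
  set.seed(99)
  p <- runif(2000, 0.1, 0.9)
  draw <- function() rbinom(2000, 1, p)
  # individuals as haplotype pairs under HWE
  h <- replicate(12, draw())
  a1 <- h[, seq(1, 11, 2)]; a2 <- h[, seq(2, 12, 2)]
  # duplicate of individual 1; offspring of individuals 1 and 2
  a1 <- cbind(a1, a1[, 1], a1[, 1])
  a2 <- cbind(a2, a2[, 1], a2[, 2])
  samples <- c(paste0("u", 1:6), "dup1", "child12")
  colnames(a1) <- colnames(a2) <- samples
  gm <- genotype_matrix(data.frame(scaffold = "s", pos = seq_len(2000L),
                                   ref = "A", alt = "T"),
                        a1, a2, samples = samples)
  phi <- pairwise_relatedness(gm)
  expect_lt(abs(phi["u1", "dup1"] - 0.5), 0.02)
  expect_lt(abs(phi["u1", "child12"] - 0.25), 0.05)
  expect_lt(abs(phi["u2", "child12"] - 0.25), 0.05)
  off_diag <- phi[paste0("u", 1:6), paste0("u", 1:6)]
  expect_lt(max(abs(off_diag[upper.tri(off_diag)])), 0.05)
  expect_equal(unname(diag(phi)), rep(0.5, 8))
})

test_that("sparse pairs are flagged low-confidence", {
  gm <- gm_from_strings(matrix("0/1", 50, 2))
  phi <- pairwise_relatedness(gm, min_sites = 100L)
  expect_true(attr(phi, "low_confidence")[1, 2])
})

test_that("collapsed populations lose heterozygosity relative to stable ones", {
  batt <- directional_battery()
  expect_gte(battery_wins(batt, "het", "lower"), 0.9)
})
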
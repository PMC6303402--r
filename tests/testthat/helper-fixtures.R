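# Small constructed fixtures used across test files.

# A genotype matrix from a compact spec: geno is a sites x samples matrix of
# strings "0/0", "0|1", "./." etc.
gm_from_strings <- function(geno, pos = seq_len(nrow(geno)) * 10L,
                            scaffold = "scaf_1", ref = "A", alt = "T",
                            gq = 99L, dp = 20L, phased = any(grepl("\\|", geno))) {
  m <- nrow(geno); n <- ncol(geno)
  a1 <- matrix(suppressWarnings(as.integer(substr(geno, 1, 1))), m, n)
  a2 <- matrix(suppressWarnings(as.integer(substr(geno, 3, 3))), m, n)
  samples <- colnames(geno)
  if (is.null(samples)) samples <- paste0("S", seq_len(n))
  colnames(a1) <- colnames(a2) <- samples
  genotype_matrix(
    data.frame(scaffold = rep(scaffold, length.out = m), pos = pos,
               ref = rep(ref, length.out = m), alt = rep(alt, length.out = m)),
    a1, a2,
    gq = matrix(gq, m, n, dimnames = list(NULL, samples)),
    dp = matrix(dp, m, n, dimnames = list(NULL, samples)),
    samples = samples, phased = phased)
}

# A variant_set built site-by-site for QC fixtures.
vs_fixture <- function(sites, a1, a2, gq, dp, samples, phased = FALSE) {
  colnames(a1) <- colnames(a2) <- colnames(gq) <- colnames(dp) <- samples
  variant_set(sites, a1, a2, gq = gq, dp = dp, samples = samples,
              phased = phased)
}

# Phased genotype matrix straight from a haplotype matrix (2n x S, 0/1).
gm_from_haplotypes <- function(hap, pos = seq_len(ncol(hap)) * 100L,
                               scaffold = "scaf_1") {
  n <- nrow(hap) / 2L
  a1 <- t(hap[seq(1, 2 * n, 2), , drop = FALSE])
  a2 <- t(hap[seq(2, 2 * n, 2), , drop = FALSE])
  samples <- paste0("S", seq_len(n))
  colnames(a1) <- colnames(a2) <- samples
  genotype_matrix(
    data.frame(scaffold = scaffold, pos = pos,
               ref = "A", alt = "T"),
    a1, a2, samples = samples, phased = TRUE)
}

# A small quick simulated pair for structural tests (not the study battery).
tiny_pair <- function(seed = 11L, mismatch = 0.02) {
  tpl <- genome_template(2L, 120000L, gene_density = 20)
  stable <- demography_config(list(c(20L, 30L)), 0, 8L, seed = seed)
  collapsed <- demography_config(list(c(12L, 6L)), 0.3, 4L, seed = seed)
  mm <- mutation_model(mu = 2.5e-6,
                       selection = c(SYN = 0, TOL = -1e-3, DEL = -0.05,
                                     LOF = -0.8))
  simulate_two_populations(tpl, stable, collapsed, mm, recomb_rate = 2e-6,
                           burn_in = 300L, outgroup_mismatch = mismatch,
                           seed = seed)
}

# QC cascade fixture: 13 samples per population, 20 SNVs + 1 indel.
cascade_fixture <- function() {
  samples <- c(sprintf("a%02d", 1:13), sprintf("b%02d", 1:13))
  n <- 26L
  m <- 21L
  pos <- c(seq(1000L, by = 1000L, length.out = 17L),  # benign SNVs
           100L,    # indel (record 18)
           103L,    # SNV within 5 bp of the indel (record 19)
           20000L,  # all-masked site (record 20)
           21000L)  # HWE-violating site (record 21)
  ref <- rep("A", m); alt <- rep("T", m)
  ref[18] <- "A"; alt[18] <- "AT"
  alt[17] <- "C,T"                                    # multiallelic SNV
  a1 <- matrix(0L, m, n); a2 <- matrix(0L, m, n)
  # benign sites: two heterozygotes per population (HWE-compatible)
  a2[, c(1, 2, 14, 15)] <- 1L
  gq <- matrix(99L, m, n); dp <- matrix(20L, m, n)
  # missingness violation at record 16: 3 missing in population A
  a1[16, 1:3] <- NA_integer_; a2[16, 1:3] <- NA_integer_
  # all-masked site
  gq[20, ] <- 5L
  # HWE violation in population A: all 13 heterozygous (p ~ 7.9e-4)
  a1[21, ] <- 0L; a2[21, ] <- 0L
  a2[21, 1:13] <- 1L
  sites <- data.frame(scaffold = "s", pos = pos, ref = ref, alt = alt)
  cfg <- filter_config(population_assignment = setNames(
    rep(c("A", "B"), each = 13), samples))
  list(vs = vs_fixture(sites, a1, a2, gq, dp, samples), cfg = cfg)
}


# Small pipeline configuration for fast end-to-end runs.
small_config <- function(seed = 1L, outdir = tempfile("erun")) {
  cfg <- default_run_config(seed = seed, outdir = outdir)
  cfg$simulation$n_scaffolds <- 2L
  cfg$simulation$scaffold_length <- 150000L
  cfg$simulation$stable_epochs <- list(c(30L, 40L))
  cfg$simulation$collapsed_epochs <- list(c(20L, 10L), c(8L, 4L))
  cfg$simulation$stable_sample <- 10L
  cfg$simulation$collapsed_sample <- 4L
  cfg$ld$max_dist <- 100000L
  cfg$ld$bin_width <- 5000L
  cfg
}
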
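#' Filter configuration for the post-calling QC cascade
#'
#' Thresholds follow the multi-sample filter cascade used for resequencing
#' panels of a bottlenecked species and its congener: biallelic SNVs only;
#' SNVs at or within `indel_pad_bp` of an indel removed; genotypes with
#' GQ < `min_gq` or depth outside (`depth_low_factor`, `depth_high_factor`)
#' times the per-sample mean depth masked; sites with more than
#' `max_missing_per_population` missing genotypes in any population removed;
#' sites deviating from Hardy-Weinberg equilibrium (exact test,
#' P < `hwe_alpha`) in any population removed.
#'
#' @param min_gq minimum genotype quality (genotypes below are masked).
#' @param depth_low_factor,depth_high_factor multiples of the per-sample mean
#'   depth outside which genotypes are masked.
#' @param indel_pad_bp SNVs at or within this distance of an indel removed.
#' @param max_missing_per_population maximum missing genotypes tolerated per
#'   population at a site.
#' @param hwe_alpha exact-test significance level for site removal.
#' @param population_assignment named character vector mapping sample name to
#'   population label.
#' @return An object of class `filter_config`.
#' @export
filter_config <- function(min_gq = 10L, depth_low_factor = 1 / 3,
                          depth_high_factor = 3, indel_pad_bp = 5L,
                          max_missing_per_population = 2L,
                          hwe_alpha = 0.001,
                          population_assignment = NULL) {
  if (!(depth_low_factor > 0 && depth_low_factor < 1 &&
        depth_high_factor > 1))
    stop("need 0 < depth_low_factor < 1 < depth_high_factor")
  structure(list(min_gq = min_gq, depth_low_factor = depth_low_factor,
                 depth_high_factor = depth_high_factor,
                 indel_pad_bp = as.integer(indel_pad_bp),
                 max_missing_per_population =
                   as.integer(max_missing_per_population),
                 hwe_alpha = hwe_alpha,
                 population_assignment = population_assignment),
            class = "filter_config")
}

#' Remove multiallelic records
#'
#' Retains only biallelic SNVs; indel records are retained separately (they
#' are needed for proximity masking) and multiallelic records of any type
#' are dropped.
#'
#' @param vs a [variant_set()].
#' @return A `variant_set` of biallelic SNVs and biallelic indels.
#' @export
remove_multiallelic <- function(vs) {
  stopifnot(inherits(vs, "variant_set"))
  multi <- grepl(",", vs$sites$alt, fixed = TRUE)
  vs_subset_sites(vs, !multi)
}

#' Remove SNVs at or within a pad of any indel
#'
#' Interval arithmetic on 1-based inclusive coordinates: the indel span is
#' `POS .. POS + nchar(ref) - 1` and SNVs with position inside
#' `[span_start - pad, span_end + pad]` are removed, boundaries included.
#' The indel records themselves are also dropped from the output (they carry
#' no SNV information downstream).
#'
#' @param vs a [variant_set()] containing SNVs and indels.
#' @param pad pad in bp (default 5).
#' @return A `variant_set` of SNVs clear of indels.
#' @export
mask_near_indels <- function(vs, pad = 5L) {
  stopifnot(inherits(vs, "variant_set"))
  if (pad < 0) stop("pad must be non-negative")
  ind <- vs$sites$is_indel
  snv <- vs_subset_sites(vs, !ind)
  if (!any(ind) || nrow(snv$sites) == 0) return(snv)
  drop <- rep(FALSE, nrow(snv$sites))
  idx <- which(ind)
  for (sc in unique(vs$sites$scaffold[idx])) {
    ii <- idx[vs$sites$scaffold[idx] == sc]
    spans <- IRanges::IRanges(vs$sites$pos[ii] - pad,
                              vs$sites$pos[ii] + nchar(vs$sites$ref[ii]) -
                                1L + pad)
    sel <- snv$sites$scaffold == sc
    qry <- IRanges::IRanges(snv$sites$pos[sel], width = 1L)
    drop[sel] <- IRanges::overlapsAny(qry, spans)
  }
  vs_subset_sites(snv, !drop)
}

#' Genotype-level quality and depth masking
#'
#' Masks (sets to missing) genotypes with GQ below `cfg$min_gq` or with depth
#' below `depth_low_factor` or above `depth_high_factor` times the sample's
#' mean depth. Mean depth is computed per sample once, over all sites of the
#' input matrix, before any masking. Sites left without any called genotype
#' are dropped (and attributed to this rule by [apply_cascade()]).
#'
#' @param vs a [variant_set()] with `gq` and `dp` matrices.
#' @param cfg a [filter_config()].
#' @return A `variant_set` with failing genotypes set to missing.
#' @export
genotype_level_filter <- function(vs, cfg = filter_config()) {
  stopifnot(inherits(vs, "variant_set"))
  if (is.null(vs$gq) || is.null(vs$dp))
    stop("genotype_level_filter requires GQ and DP")
  mean_dp <- colMeans(vs$dp, na.rm = TRUE)
  if (anyNA(mean_dp) || any(!is.finite(mean_dp)))
    stop("sample with no depth information: ",
         paste(vs$samples[!is.finite(mean_dp)], collapse = ", "))
  lo <- matrix(cfg$depth_low_factor * mean_dp, nrow(vs$dp),
               length(mean_dp), byrow = TRUE)
  hi <- matrix(cfg$depth_high_factor * mean_dp, nrow(vs$dp),
               length(mean_dp), byrow = TRUE)
  bad <- (!is.na(vs$gq) & vs$gq < cfg$min_gq) |
         (!is.na(vs$dp) & (vs$dp < lo | vs$dp > hi))
  vs$a1[bad] <- NA_integer_
  vs$a2[bad] <- NA_integer_
  vs
}

#' Per-population missingness filter
#'
#' Removes sites with more than `cfg$max_missing_per_population` missing
#' genotypes in any population.
#'
#' @param vs a [variant_set()].
#' @param cfg a [filter_config()] whose `population_assignment` covers every
#'   sample.
#' @return A `variant_set`.
#' @export
missingness_filter <- function(vs, cfg) {
  pops <- cfg$population_assignment[vs$samples]
  if (is.null(cfg$population_assignment) || anyNA(pops))
    stop("population_assignment must cover every sample")
  miss <- is.na(vs$a1) | is.na(vs$a2)
  bad <- rep(FALSE, nrow(vs$sites))
  for (p in unique(pops)) {
    cnt <- rowSums(miss[, pops == p, drop = FALSE])
    bad <- bad | cnt > cfg$max_missing_per_population
  }
  vs_subset_sites(vs, !bad)
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided exact test on diploid genotype counts: conditional on the
#' observed allele counts, heterozygote counts of the same parity follow the
#' classical hypergeometric-type law; the p-value sums the probabilities of
#' all heterozygote counts whose probability does not exceed the observed
#' one. Monomorphic sites return 1 by convention.
#'
#' @param n_aa,n_ab,n_bb genotype counts (hom ref, het, hom alt).
#' @return Exact two-sided p-value.
#' @export
hwe_exact_test <- function(n_aa, n_ab, n_bb) {
  stopifnot(n_aa >= 0, n_ab >= 0, n_bb >= 0)
  n <- n_aa + n_ab + n_bb
  if (n < 1) stop("at least one genotype required")
  na <- 2L * n_aa + n_ab      # ref alleles
  nb <- 2L * n_bb + n_ab      # alt alleles
  if (na == 0L || nb == 0L) return(1.0)
  rare <- min(na, nb)
  hets <- seq(rare %% 2L, rare, by = 2L)
  # recurrence: P(h+2)/P(h) = 4 * n_ra(h) * n_cm(h) / ((h+2)*(h+1)),
  # where n_ra, n_cm are the homozygote counts implied by h
  probs <- numeric(length(hets))
  probs[1] <- 1
  for (k in seq_along(hets)[-1]) {
    h <- hets[k - 1]
    n_ra <- (rare - h) / 2
    n_cm <- (max(na, nb) - h) / 2
    probs[k] <- probs[k - 1] * 4 * n_ra * n_cm / ((h + 2) * (h + 1))
  }
  probs <- probs / sum(probs)
  obs <- probs[match(n_ab, hets)]
  sum(probs[probs <= obs * (1 + 1e-12)])
}

#' Apply the full QC cascade
#'
#' Applies the filters in the frozen order: multiallelic removal ->
#' indel-proximity masking -> genotype-level GQ/depth masking (sites left
#' all-missing dropped here) -> per-population missingness -> exact HWE per
#' population (removed when P < `hwe_alpha` in any population). Each removed
#' site is attributed to the first rule that failed it and the report counts
#' balance exactly against the input.
#'
#' @param vs a [variant_set()] straight from [read_vcf()].
#' @param cfg a [filter_config()] with `population_assignment`.
#' @return A list with `gm` (filtered, biallelic [genotype_matrix()]) and
#'   `report` (class `filter_report`).
#' @export
apply_cascade <- function(vs, cfg) {
  stopifnot(inherits(vs, "variant_set"), inherits(cfg, "filter_config"))
  n_input <- nrow(vs$sites)
  n_indel <- sum(vs$sites$is_indel &
                 !grepl(",", vs$sites$alt, fixed = TRUE))
  s1 <- remove_multiallelic(vs)
  n_multi <- n_input - nrow(s1$sites)
  s2 <- mask_near_indels(s1, cfg$indel_pad_bp)
  n_near_indel <- nrow(s1$sites) - n_indel - nrow(s2$sites)
  s3 <- genotype_level_filter(s2, cfg)
  n_masked <- sum((is.na(s3$a1) | is.na(s3$a2)) &
                  !(is.na(s2$a1) | is.na(s2$a2)))
  all_missing <- rowSums(!is.na(s3$a1) & !is.na(s3$a2)) == 0
  n_all_missing <- sum(all_missing)
  s3 <- vs_subset_sites(s3, !all_missing)
  s4 <- missingness_filter(s3, cfg)
  n_missing <- nrow(s3$sites) - nrow(s4$sites)
  # HWE per population
  pops <- cfg$population_assignment[s4$samples]
  bad <- rep(FALSE, nrow(s4$sites))
  for (p in unique(pops)) {
    dos <- s4$a1[, pops == p, drop = FALSE] +
           s4$a2[, pops == p, drop = FALSE]
    for (i in seq_len(nrow(s4$sites))) {
      d <- dos[i, ]
      d <- d[!is.na(d)]
      if (length(d) == 0) next
      pv <- hwe_exact_test(sum(d == 0L), sum(d == 1L), sum(d == 2L))
      if (pv < cfg$hwe_alpha) bad[i] <- TRUE
    }
  }
  s5 <- vs_subset_sites(s4, !bad)
  n_hwe <- sum(bad)
  report <- structure(list(
    n_input = n_input,
    removed = c(multiallelic = n_multi, indel_record = n_indel,
                near_indel = n_near_indel,
                genotype_level_site = n_all_missing,
                missingness = n_missing, hwe = n_hwe),
    genotypes_masked = n_masked,
    n_surviving = nrow(s5$sites)), class = "filter_report")
  stopifnot(report$n_input == report$n_surviving + sum(report$removed))
  list(gm = as_genotype_matrix(s5), report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("filter_report: %d sites in, %d surviving\n", x$n_input,
              x$n_surviving))
  for (r in names(x$removed))
    cat(sprintf("  removed %-20s %d\n", r, x$removed[[r]]))
  cat(sprintf("  genotypes masked       %d\n", x$genotypes_masked))
  invisible(x)
}
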
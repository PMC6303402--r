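# Per-site unbiased diversity: d(n-d)/C(n,2) at a site with n non-missing
# alleles and d alt alleles; equals the mean pairwise difference over all
# haplotype pairs.
site_pi <- function(alt_count, n_alleles) {
  out <- numeric(length(alt_count))
  ok <- n_alleles >= 2
  out[ok] <- alt_count[ok] * (n_alleles[ok] - alt_count[ok]) /
    choose(n_alleles[ok], 2)
  out
}

site_allele_counts <- function(gm) {
  alt <- rowSums(gm$a1 == 1L, na.rm = TRUE) +
         rowSums(gm$a2 == 1L, na.rm = TRUE)
  n <- rowSums(!is.na(gm$a1)) + rowSums(!is.na(gm$a2))
  list(alt = alt, n = n)
}

#' Windowed nucleotide diversity
#'
#' Sliding-window pi with an unbiased per-site estimator: at each site,
#' `d(n-d)/choose(n,2)` with `n` the non-missing allele count and `d` the
#' alt count (the mean pairwise haplotype difference), summed per window and
#' divided by the window's accessible length. With no accessibility mask the
#' accessible length is the window's span clipped at the scaffold end;
#' windows below `min_accessible` bp are flagged.
#'
#' @param gm a [genotype_matrix()].
#' @param window,step window and step sizes in bp (defaults 50 kb / 10 kb).
#' @param scaffold_lengths named vector; defaults to the largest observed
#'   position per scaffold.
#' @param min_accessible windows with fewer accessible bp are flagged.
#' @return data.frame with `scaffold`, `start`, `end` (0-based half-open),
#'   `n_accessible_bp`, `n_snv`, `pi`, `flagged`.
#' @export
windowed_pi <- function(gm, window = 50000L, step = 10000L,
                        scaffold_lengths = NULL, min_accessible = 1L) {
  if (window < step) stop("window must be >= step")
  if (n_sites(gm) == 0)
    return(data.frame(scaffold = character(0), start = integer(0),
                      end = integer(0), n_accessible_bp = integer(0),
                      n_snv = integer(0), pi = numeric(0),
                      flagged = logical(0)))
  if (is.null(scaffold_lengths)) {
    scaffold_lengths <- tapply(gm$sites$pos, gm$sites$scaffold, max)
    scaffold_lengths <- setNames(as.integer(scaffold_lengths),
                                 names(scaffold_lengths))
  }
  ac <- site_allele_counts(gm)
  pi_site <- site_pi(ac$alt, ac$n)
  seg <- ac$alt > 0 & ac$alt < ac$n
  out <- list()
  for (sc in names(scaffold_lengths)) {
    L <- scaffold_lengths[[sc]]
    sel <- which(gm$sites$scaffold == sc)
    sel <- sel[order(gm$sites$pos[sel])]
    pos <- gm$sites$pos[sel]
    cpi <- cumsum(pi_site[sel])
    cseg <- cumsum(as.integer(seg[sel]))
    starts <- seq(0L, max(0L, L - 1L), by = step)
    starts <- starts[starts < L]
    ends <- pmin(starts + window, L)
    lo <- findInterval(starts, pos)       # sites with pos <= start (0-based)
    hi <- findInterval(ends, pos)         # sites with pos <= end
    sum_in <- function(cv) ifelse(hi > 0, cv[pmax(hi, 1L)], 0) -
      ifelse(lo > 0, cv[pmax(lo, 1L)], 0)
    acc <- ends - starts
    out[[sc]] <- data.frame(scaffold = sc, start = starts, end = ends,
                            n_accessible_bp = acc,
                            n_snv = as.integer(sum_in(cseg)),
                            pi = sum_in(cpi) / pmax(acc, 1L),
                            flagged = acc < min_accessible)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-individual heterozygosity by genomic region class
#'
#' Counts heterozygous genotypes per individual within each region class of
#' a [region_class_map()] and divides by the accessible genotyped length of
#' the class (class bp minus the individual's missing variant genotypes in
#' the class; invariant bases count as genotyped reference-homozygous).
#' A `genome` row gives the genome-wide value. Classes with no accessible
#' length give `NA` with `flagged = TRUE`.
#'
#' @param gm a [genotype_matrix()].
#' @param regions a [region_class_map()].
#' @return data.frame with `individual`, `region`, `n_het`, `accessible_bp`,
#'   `heterozygosity`, `flagged`.
#' @export
heterozygosity_by_region <- function(gm, regions) {
  cls <- region_lookup(regions, gm$sites$scaffold, gm$sites$pos)
  lens <- region_class_lengths(regions)
  het <- geno_is_het(gm)
  miss <- geno_is_missing(gm)
  classes <- c(names(lens), "genome")
  lens <- c(lens, genome = sum(lens))
  rows <- list()
  for (j in seq_along(gm$samples)) {
    for (rc in classes) {
      in_class <- if (rc == "genome") rep(TRUE, length(cls)) else
        !is.na(cls) & cls == rc
      nh <- sum(het[in_class, j], na.rm = TRUE)
      acc <- lens[[rc]] - sum(miss[in_class, j])
      rows[[length(rows) + 1L]] <- data.frame(
        individual = gm$samples[j], region = rc, n_het = nh,
        accessible_bp = acc,
        heterozygosity = if (acc > 0) nh / acc else NA_real_,
        flagged = acc <= 0)
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Site frequency spectrum
#'
#' Unfolded (derived-allele) SFS when ancestral states are supplied, folded
#' (minor-allele) otherwise. Sites whose ancestral allele matches neither
#' ref nor alt are excluded and counted. Sites with missing genotypes are
#' excluded by default, or projected to a fixed haploid sample size by
#' hypergeometric down-sampling (`on_missing = "project"`), which yields
#' fractional expected counts.
#'
#' @param gm a [genotype_matrix()].
#' @param ancestral optional character vector of ancestral alleles, one per
#'   site (see [polarize()]), for the unfolded spectrum.
#' @param on_missing `"exclude"` (default) or `"project"`.
#' @param n_project haploid size to project to (required for `"project"`).
#' @return An `sfs` object: `counts` (bins 1 .. n_hap - 1), `n_hap`,
#'   `folded`, `n_excluded_missing`, `n_excluded_ancestral`,
#'   `n_monomorphic`.
#' @export
site_frequency_spectrum <- function(gm, ancestral = NULL,
                                    on_missing = c("exclude", "project"),
                                    n_project = NULL) {
  on_missing <- match.arg(on_missing)
  folded <- is.null(ancestral)
  n_hap_full <- 2L * n_samples(gm)
  ac <- site_allele_counts(gm)
  n_exc_anc <- 0L
  der <- ac$alt
  keep <- rep(TRUE, n_sites(gm))
  if (!folded) {
    stopifnot(length(ancestral) == n_sites(gm))
    anc_is_ref <- ancestral == gm$sites$ref
    anc_is_alt <- ancestral == gm$sites$alt
    bad <- !(anc_is_ref | anc_is_alt) | is.na(ancestral)
    n_exc_anc <- sum(bad)
    keep <- !bad
    der <- ifelse(anc_is_alt, ac$n - ac$alt, ac$alt)
  }
  m <- if (on_missing == "project") {
    if (is.null(n_project)) stop("n_project required when projecting")
    as.integer(n_project)
  } else n_hap_full
  counts <- numeric(max(m - 1L, 0L))
  has_missing <- ac$n < n_hap_full
  n_exc_miss <- 0L
  n_mono <- 0L
  for (i in which(keep)) {
    ni <- ac$n[i]; di <- der[i]
    if (ni < m || (on_missing == "exclude" && has_missing[i])) {
      n_exc_miss <- n_exc_miss + 1L
      next
    }
    if (di == 0 || di == ni) { n_mono <- n_mono + 1L; next }
    if (ni == m) {
      k <- if (folded) min(di, ni - di) else di
      if (k >= 1 && k <= m - 1) counts[k] <- counts[k] + 1
    } else {
      k <- seq_len(m - 1L)
      w <- stats::dhyper(k, di, ni - di, m)
      if (folded) {
        kf <- pmin(k, m - k)
        counts[seq_len(max(kf))] <- counts[seq_len(max(kf))] +
          as.numeric(tapply(w, kf, sum))[seq_len(max(kf))]
      } else counts <- counts + w
    }
  }
  if (folded) counts <- counts[seq_len(floor(m / 2))]
  structure(list(counts = setNames(counts, seq_along(counts)), n_hap = m,
                 folded = folded, n_excluded_missing = n_exc_miss,
                 n_excluded_ancestral = n_exc_anc, n_monomorphic = n_mono),
            class = "sfs")
}

#' @export
print.sfs <- function(x, ...) {
  cat(sprintf("%s SFS, n_hap = %d, %d sites\n",
              if (x$folded) "folded" else "unfolded", x$n_hap,
              round(sum(x$counts))))
  invisible(x)
}

tajima_constants <- function(n) {
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Tajima's D
#'
#' Standard normalized difference between the pairwise-diversity and
#' segregating-sites estimators of theta. With complete genotypes this is
#' the textbook statistic at `n = 2 x samples` haplotypes; with missing
#' genotypes every site is down-projected to the smallest observed allele
#' count (the expected number of projected segregating sites replaces S).
#' Sites with fewer than 4 non-missing alleles are dropped. `S = 0` (or
#' fewer than 4 haplotypes) gives `NA`.
#'
#' @param gm a [genotype_matrix()].
#' @return Tajima's D (scalar), `NA` when undefined.
#' @export
tajimas_d <- function(gm) {
  ac <- site_allele_counts(gm)
  ok <- ac$n >= 4L
  if (!any(ok)) return(NA_real_)
  n_proj <- min(ac$n[ok])
  alt <- ac$alt[ok]; nn <- ac$n[ok]
  pi_tot <- sum(site_pi(alt, nn))
  # probability a site remains segregating when projected to n_proj alleles
  p_seg <- 1 - (exp(lchoose(alt, n_proj) - lchoose(nn, n_proj)) +
                exp(lchoose(nn - alt, n_proj) - lchoose(nn, n_proj)))
  p_seg[alt == 0 | alt == nn] <- 0
  S <- sum(p_seg)
  if (S <= 0) return(NA_real_)
  k <- tajima_constants(n_proj)
  (pi_tot - S / k$a1) / sqrt(k$e1 * S + k$e2 * S * (S - 1))
}

#' Windowed Tajima's D
#'
#' @param gm a [genotype_matrix()].
#' @param window,step window and step in bp.
#' @param scaffold_lengths named vector of scaffold lengths.
#' @return data.frame of windows with a `tajimas_d` column (`NA` when
#'   undefined in a window).
#' @export
tajimas_d_windows <- function(gm, window = 50000L, step = 10000L,
                              scaffold_lengths = NULL) {
  win <- windowed_pi(gm, window, step, scaffold_lengths)
  win$tajimas_d <- vapply(seq_len(nrow(win)), function(i) {
    sel <- gm$sites$scaffold == win$scaffold[i] &
      gm$sites$pos > win$start[i] & gm$sites$pos <= win$end[i]
    if (!any(sel)) return(NA_real_)
    tajimas_d(gm_subset_sites(gm, sel))
  }, numeric(1))
  win
}

#' Pairwise kinship (KING-robust style)
#'
#' Identity-by-state kinship from genotype dosages:
#' `phi = (n_both_het - 2 * n_opposite_hom) / (n_het_i + n_het_j)` over
#' co-genotyped sites. Duplicated samples (and self-kinship, by convention)
#' give ~0.5, parent-offspring ~0.25, unrelated ~0. Pairs with fewer than
#' `min_sites` co-genotyped sites are flagged low-confidence.
#'
#' @param gm a [genotype_matrix()].
#' @param min_sites minimum co-genotyped sites for a confident estimate.
#' @return A symmetric matrix of kinship values with attributes `n_co`
#'   (co-genotyped site counts) and `low_confidence` (logical matrix).
#' @export
pairwise_relatedness <- function(gm, min_sites = 100L) {
  n <- n_samples(gm)
  if (n < 2) stop("need at least two individuals")
  d <- geno_dosage(gm)
  phi <- matrix(NA_real_, n, n, dimnames = list(gm$samples, gm$samples))
  nco <- matrix(0L, n, n, dimnames = dimnames(phi))
  diag(phi) <- 0.5
  diag(nco) <- colSums(!is.na(d))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- !is.na(d[, i]) & !is.na(d[, j])
      di <- d[ok, i]; dj <- d[ok, j]
      nhi <- sum(di == 1L); nhj <- sum(dj == 1L)
      both <- sum(di == 1L & dj == 1L)
      opp <- sum(abs(di - dj) == 2L)
      phi[i, j] <- phi[j, i] <-
        if (nhi + nhj > 0) (both - 2 * opp) / (nhi + nhj) else NA_real_
      nco[i, j] <- nco[j, i] <- sum(ok)
    }
  }
  attr(phi, "n_co") <- nco
  attr(phi, "low_confidence") <- nco < min_sites
  phi
}
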
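#' Polarize variants against outgroup genotypes
#'
#' A site's polarity is called only when all `k` outgroup samples (default,
#' and conventionally, three) are homozygous for the same allele; that
#' allele is the ancestral state and the other the derived. Any other
#' pattern is excluded with a reason code: `discordant_outgroups`
#' (conflicting or heterozygous outgroups), `missing_outgroups`, or
#' `ancestral_not_in_alleles` (shared outgroup allele matches neither ref
#' nor alt — impossible when outgroups share the site's allele coding, but
#' reported for generality).
#'
#' @param gm a [genotype_matrix()] of the ingroup (defines the site set).
#' @param outgroups a [genotype_matrix()] of the outgroup samples over the
#'   same sites.
#' @param k required number of outgroup samples (default 3).
#' @return data.frame with `scaffold`, `pos`, `status`, `ancestral`,
#'   `derived` (`NA` alleles when not polarized).
#' @export
polarize <- function(gm, outgroups, k = 3L) {
  if (n_samples(outgroups) != k)
    stop("expected ", k, " outgroup samples, got ", n_samples(outgroups))
  key_in <- site_key(gm)
  idx <- match(key_in, site_key(outgroups))
  if (anyNA(idx)) stop("outgroup genotypes missing for some sites")
  a1 <- outgroups$a1[idx, , drop = FALSE]
  a2 <- outgroups$a2[idx, , drop = FALSE]
  miss <- rowSums(is.na(a1) | is.na(a2)) > 0
  hom <- !miss & rowSums(a1 != a2) == 0
  agree <- hom & apply(a1, 1, function(r) length(unique(r)) == 1L)
  status <- rep("discordant_outgroups", n_sites(gm))
  status[miss] <- "missing_outgroups"
  anc <- rep(NA_character_, n_sites(gm))
  der <- rep(NA_character_, n_sites(gm))
  pol <- which(agree)
  if (length(pol)) {
    code <- a1[pol, 1]
    anc[pol] <- ifelse(code == 0L, gm$sites$ref[pol], gm$sites$alt[pol])
    der[pol] <- ifelse(code == 0L, gm$sites$alt[pol], gm$sites$ref[pol])
    status[pol] <- "polarized"
  }
  data.frame(scaffold = gm$sites$scaffold, pos = gm$sites$pos,
             status = status, ancestral = anc, derived = der,
             stringsAsFactors = FALSE)
}

#' Assign SYN/TOL/DEL/LoF effect categories
#'
#' Deterministic rule over the annotation class and three effect-predictor
#' verdicts: `lof` annotations are LOF; `synonymous` are SYN regardless of
#' verdicts; `missense` are DEL only when all three predictors call the
#' variant deleterious (the intersection rule), otherwise TOL. Missense
#' sites with a missing verdict are left undetermined (`NA`).
#'
#' @param effects data.frame with `annotation`
#'   (synonymous/missense/lof) and three verdict columns (values
#'   "del"/"benign"), e.g. from [simulate_effect_calls()].
#' @param verdict_cols names of the three predictor columns.
#' @return The input with a `category` column added.
#' @export
assign_category <- function(effects,
                            verdict_cols = c("polyphen", "provean", "sift")) {
  stopifnot(all(verdict_cols %in% names(effects)),
            length(verdict_cols) == 3L)
  v <- as.matrix(effects[verdict_cols])
  all_del <- rowSums(v == "del") == 3L
  any_na <- rowSums(is.na(v)) > 0L
  category <- rep(NA_character_, nrow(effects))
  category[effects$annotation == "lof"] <- "LOF"
  category[effects$annotation == "synonymous"] <- "SYN"
  mis <- effects$annotation == "missense"
  category[mis & !any_na] <- ifelse(all_del[mis & !any_na], "DEL", "TOL")
  effects$category <- category
  effects
}

#' Per-individual genetic-load summaries
#'
#' For every individual and category, counts heterozygous,
#' homozygous-derived and homozygous-ancestral genotypes among polarized
#' sites and the derived allele count (each heterozygote once, each
#' homozygous-derived genotype twice). Only sites with `status ==
#' "polarized"` and a non-missing category are tallied; with a gene map the
#' number of genes carrying at least one homozygous-derived variant is
#' added.
#'
#' @param gm a [genotype_matrix()].
#' @param polarized output of [polarize()] over the same sites.
#' @param categories output of [assign_category()] (matched by
#'   scaffold/pos).
#' @param genes optional CDS exon table for per-category gene counts.
#' @return data.frame with one row per individual x category.
#' @export
count_load <- function(gm, polarized, categories, genes = NULL) {
  stopifnot(nrow(polarized) == n_sites(gm))
  cat_idx <- match(site_key(gm), site_key(categories))
  category <- categories$category[cat_idx]
  use <- polarized$status == "polarized" & !is.na(category)
  der_is_alt <- polarized$ancestral == gm$sites$ref
  dos <- geno_dosage(gm)
  # derived dosage: flip when the reference allele is derived
  ddos <- dos
  flip <- which(use & !der_is_alt)
  ddos[flip, ] <- 2L - dos[flip, , drop = FALSE]
  gene_of <- NULL
  if (!is.null(genes)) {
    gene_of <- rep(NA_character_, n_sites(gm))
    for (sc in unique(genes$scaffold)) {
      gsel <- genes$scaffold == sc
      msel <- which(gm$sites$scaffold == sc)
      if (!length(msel)) next
      ov <- IRanges::findOverlaps(
        IRanges::IRanges(gm$sites$pos[msel], width = 1L),
        IRanges::IRanges(genes$start[gsel], genes$end[gsel]),
        select = "first")
      gene_of[msel] <- genes$gene_id[gsel][ov]
    }
  }
  cats <- c("SYN", "TOL", "DEL", "LOF")
  rows <- list()
  for (j in seq_along(gm$samples)) {
    dj <- ddos[, j]
    for (cc in cats) {
      sel <- use & category == cc
      n_het <- sum(dj[sel] == 1L, na.rm = TRUE)
      n_hom_der <- sum(dj[sel] == 2L, na.rm = TRUE)
      n_hom_anc <- sum(dj[sel] == 0L, na.rm = TRUE)
      n_missing <- sum(is.na(dj[sel]))
      row <- data.frame(individual = gm$samples[j], category = cc,
                        n_sites = sum(sel), n_het = n_het,
                        n_hom_derived = n_hom_der,
                        n_hom_ancestral = n_hom_anc,
                        n_missing = n_missing,
                        derived_allele_count = n_het + 2L * n_hom_der)
      if (!is.null(gene_of))
        row$n_genes_hom_derived <-
          length(unique(gene_of[sel & !is.na(gene_of) & !is.na(dj) &
                                  dj == 2L]))
      rows[[length(rows) + 1L]] <- row
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum test. For `max(n1, n2) <= 8` the p-value is exact, by
#' enumeration of all group assignments of the observed values (valid under
#' ties); otherwise the tie-corrected normal approximation with continuity
#' correction is used.
#'
#' @param x,y numeric samples.
#' @return list with `U` (for the first sample), `p_value`, `method`.
#' @export
mw_test <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  stopifnot(n1 >= 1, n2 >= 1)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (max(n1, n2) <= 8) {
    v <- c(x, y)
    stat_for <- function(idx) {
      rr <- rank(v)
      sum(rr[idx]) - n1 * (n1 + 1) / 2
    }
    combs <- combn(n1 + n2, n1)
    mu <- n1 * n2 / 2
    obs_dev <- abs(U - mu)
    us <- apply(combs, 2, stat_for)
    p <- mean(abs(us - mu) >= obs_dev - 1e-9)
    return(list(U = U, p_value = p, method = "exact enumeration"))
  }
  ties <- table(r)
  mu <- n1 * n2 / 2
  n <- n1 + n2
  sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  z <- (abs(U - mu) - 0.5) / sqrt(sigma2)
  p <- min(1, 2 * stats::pnorm(z, lower.tail = FALSE))
  list(U = U, p_value = p, method = "normal approximation")
}

#' Compare load summaries between populations
#'
#' For every category and load metric, a two-sided Mann-Whitney U test
#' between the two groups of individuals plus group medians and the
#' difference of means.
#'
#' @param summaries output of [count_load()] (possibly from two datasets
#'   combined with `rbind`).
#' @param grouping named character vector: individual -> population label
#'   (exactly two labels).
#' @param metrics which columns to compare.
#' @return data.frame with one row per category x metric.
#' @export
compare_populations <- function(summaries, grouping,
                                metrics = c("n_het", "n_hom_derived",
                                            "derived_allele_count")) {
  g <- grouping[summaries$individual]
  if (anyNA(g)) stop("grouping must cover every individual")
  labs <- unique(grouping)
  if (length(labs) != 2) stop("exactly two populations required")
  rows <- list()
  for (cc in unique(summaries$category)) {
    for (met in metrics) {
      s <- summaries[summaries$category == cc, , drop = FALSE]
      gg <- grouping[s$individual]
      x <- s[[met]][gg == labs[1]]
      y <- s[[met]][gg == labs[2]]
      if (length(x) < 2 || length(y) < 2)
        stop("need >= 2 individuals per population")
      tst <- mw_test(x, y)
      rows[[length(rows) + 1L]] <- data.frame(
        category = cc, metric = met,
        group1 = labs[1], group2 = labs[2],
        median1 = median(x), median2 = median(y),
        mean_diff = mean(x) - mean(y),
        U = tst$U, p_value = tst$p_value, method = tst$method)
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Site frequency spectra by effect category
#'
#' One unfolded SFS per category over polarized sites, plus proportions for
#' cross-category comparison. Empty categories give empty spectra (flagged
#' by a zero total).
#'
#' @inheritParams count_load
#' @param ... passed to [site_frequency_spectrum()].
#' @return Named list of `sfs` objects (one per category, plus `ALL`), each
#'   with a `proportions` element added.
#' @export
sfs_by_category <- function(gm, polarized, categories, ...) {
  cat_idx <- match(site_key(gm), site_key(categories))
  category <- categories$category[cat_idx]
  use <- polarized$status == "polarized" & !is.na(category)
  out <- list()
  for (cc in c("SYN", "TOL", "DEL", "LOF", "ALL")) {
    sel <- if (cc == "ALL") use else use & category == cc
    sub <- gm_subset_sites(gm, sel)
    sf <- site_frequency_spectrum(sub, ancestral = polarized$ancestral[sel],
                                  ...)
    tot <- sum(sf$counts)
    sf$proportions <- if (tot > 0) sf$counts / tot else sf$counts
    out[[cc]] <- sf
  }
  out
}
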
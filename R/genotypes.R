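#' Diploid genotype matrix
#'
#' The spine of every analysis stage: biallelic SNVs in rows of `sites`
#' (scaffold, 1-based position, ref and alt alleles) with two integer allele
#' matrices `a1`/`a2` (sites x samples; 0 = ref, 1 = alt, `NA` = missing) and
#' optional per-genotype quality (`gq`) and depth (`dp`) matrices.
#'
#' @param sites data.frame with columns `scaffold`, `pos`, `ref`, `alt`.
#' @param a1,a2 integer matrices of first/second allele per genotype.
#' @param gq,dp optional integer matrices (genotype quality, read depth).
#' @param samples character vector of sample names (one per column).
#' @param phased logical; `TRUE` when `a1`/`a2` are haplotype-resolved.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(sites, a1, a2, gq = NULL, dp = NULL,
                            samples = colnames(a1), phased = FALSE) {
  stopifnot(is.data.frame(sites),
            all(c("scaffold", "pos", "ref", "alt") %in% names(sites)),
            is.matrix(a1), is.matrix(a2),
            nrow(a1) == nrow(sites), all(dim(a1) == dim(a2)))
  if (is.null(samples)) samples <- paste0("S", seq_len(ncol(a1)))
  bad <- (!is.na(a1) & !(a1 %in% c(0L, 1L))) |
         (!is.na(a2) & !(a2 %in% c(0L, 1L)))
  if (any(bad)) stop("genotype alleles must be 0 (ref), 1 (alt) or NA")
  if (any(sites$pos < 1L)) stop("positions must be >= 1")
  if (any(sites$ref == sites$alt)) stop("ref and alt alleles must differ")
  rownames(sites) <- NULL
  structure(list(sites = sites,
                 a1 = a1, a2 = a2, gq = gq, dp = dp,
                 samples = as.character(samples),
                 phased = isTRUE(phased)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d sites x %d samples (%s)\n",
              n_sites(x), n_samples(x),
              if (x$phased) "phased" else "unphased"))
  invisible(x)
}

#' @rdname genotype_matrix
#' @param gm a `genotype_matrix`.
#' @export
n_sites <- function(gm) nrow(gm$sites)

#' @rdname genotype_matrix
#' @export
n_samples <- function(gm) length(gm$samples)

#' Per-genotype summaries
#'
#' `geno_dosage` returns the alt-allele dosage matrix (0/1/2, NA when
#' missing); `geno_is_het` and `geno_is_missing` the corresponding logical
#' matrices.
#'
#' @param gm a `genotype_matrix`.
#' @return A sites x samples matrix.
#' @export
geno_dosage <- function(gm) gm$a1 + gm$a2

#' @rdname geno_dosage
#' @export
geno_is_het <- function(gm) gm$a1 != gm$a2

#' @rdname geno_dosage
#' @export
geno_is_missing <- function(gm) is.na(gm$a1) | is.na(gm$a2)

#' Subset a genotype matrix
#'
#' @param gm a `genotype_matrix`.
#' @param i site index (logical or integer) for `gm_subset_sites`;
#'   sample index or names for `gm_subset_samples`.
#' @return A `genotype_matrix`.
#' @export
gm_subset_sites <- function(gm, i) {
  genotype_matrix(gm$sites[i, , drop = FALSE],
                  gm$a1[i, , drop = FALSE], gm$a2[i, , drop = FALSE],
                  gq = if (!is.null(gm$gq)) gm$gq[i, , drop = FALSE],
                  dp = if (!is.null(gm$dp)) gm$dp[i, , drop = FALSE],
                  samples = gm$samples, phased = gm$phased)
}

#' @rdname gm_subset_sites
#' @export
gm_subset_samples <- function(gm, i) {
  if (is.character(i)) i <- match(i, gm$samples)
  if (anyNA(i)) stop("unknown sample name")
  genotype_matrix(gm$sites,
                  gm$a1[, i, drop = FALSE], gm$a2[, i, drop = FALSE],
                  gq = if (!is.null(gm$gq)) gm$gq[, i, drop = FALSE],
                  dp = if (!is.null(gm$dp)) gm$dp[, i, drop = FALSE],
                  samples = gm$samples[i], phased = gm$phased)
}

#' Haplotype matrix from phased genotypes
#'
#' Interleaves `a1`/`a2` columns into a sites x (2 * samples) matrix of
#' 0/1 alleles. Requires phased data.
#'
#' @param gm a phased `genotype_matrix`.
#' @return Integer matrix with two columns per sample.
#' @export
haplotypes <- function(gm) {
  if (!gm$phased) stop("haplotypes() requires phased genotypes")
  n <- n_samples(gm)
  hap <- matrix(NA_integer_, n_sites(gm), 2L * n)
  hap[, 2L * seq_len(n) - 1L] <- gm$a1
  hap[, 2L * seq_len(n)] <- gm$a2
  colnames(hap) <- paste0(rep(gm$samples, each = 2L), c("_1", "_2"))
  hap
}

#' Raw variant records prior to QC
#'
#' Holds possibly multiallelic SNVs and indels as read from a VCF: `alt` may
#' contain comma-separated alternates and allele codes in `a1`/`a2` index
#' into `c(ref, alts)` (0 = ref). The QC cascade consumes a `variant_set`
#' and emits a clean biallelic [genotype_matrix()].
#'
#' @param sites data.frame with `scaffold`, `pos`, `ref`, `alt` (alt may be
#'   comma-separated), and logical `is_indel`.
#' @inheritParams genotype_matrix
#' @return An object of class `variant_set`.
#' @export
variant_set <- function(sites, a1, a2, gq = NULL, dp = NULL,
                        samples = colnames(a1), phased = FALSE) {
  stopifnot(is.data.frame(sites),
            all(c("scaffold", "pos", "ref", "alt") %in% names(sites)))
  if (is.null(sites$is_indel))
    sites$is_indel <- nchar(sites$ref) > 1L |
      vapply(strsplit(sites$alt, ",", fixed = TRUE),
             function(a) any(nchar(a) != 1L), logical(1))
  if (is.null(samples)) samples <- paste0("S", seq_len(ncol(a1)))
  rownames(sites) <- NULL
  structure(list(sites = sites, a1 = a1, a2 = a2, gq = gq, dp = dp,
                 samples = as.character(samples), phased = isTRUE(phased)),
            class = "variant_set")
}

#' @export
print.variant_set <- function(x, ...) {
  cat(sprintf("variant_set: %d records x %d samples (%d indels)\n",
              nrow(x$sites), length(x$samples), sum(x$sites$is_indel)))
  invisible(x)
}

vs_subset_sites <- function(vs, i) {
  vs$sites <- vs$sites[i, , drop = FALSE]
  rownames(vs$sites) <- NULL
  vs$a1 <- vs$a1[i, , drop = FALSE]
  vs$a2 <- vs$a2[i, , drop = FALSE]
  if (!is.null(vs$gq)) vs$gq <- vs$gq[i, , drop = FALSE]
  if (!is.null(vs$dp)) vs$dp <- vs$dp[i, , drop = FALSE]
  vs
}

#' Convert clean variant records to a genotype matrix
#'
#' Fails unless every record is a biallelic SNV (run the QC cascade, or at
#' least [remove_multiallelic()], first).
#'
#' @param vs a `variant_set`.
#' @return A [genotype_matrix()].
#' @export
as_genotype_matrix <- function(vs) {
  stopifnot(inherits(vs, "variant_set"))
  if (any(vs$sites$is_indel)) stop("variant_set still contains indels")
  if (any(grepl(",", vs$sites$alt, fixed = TRUE)))
    stop("variant_set still contains multiallelic records")
  genotype_matrix(vs$sites[c("scaffold", "pos", "ref", "alt")],
                  vs$a1, vs$a2, gq = vs$gq, dp = vs$dp,
                  samples = vs$samples, phased = vs$phased)
}

#' Site identifiers
#'
#' `"scaffold:pos"` keys used to match sites between the genotype matrix,
#' polarization table, effect calls and truth table.
#'
#' @param x a `genotype_matrix`, `variant_set` or data.frame with
#'   `scaffold`/`pos` columns.
#' @return Character vector of keys.
#' @export
site_key <- function(x) {
  if (is.data.frame(x)) paste(x$scaffold, x$pos, sep = ":")
  else paste(x$sites$scaffold, x$sites$pos, sep = ":")
}
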
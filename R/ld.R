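#' Pairwise linkage disequilibrium (r-squared)
#'
#' Computes `r^2 = D^2 / (pA pa pB pb)` from haplotype frequencies for every
#' intra-scaffold site pair within `max_dist` bp (phased input), or the
#' squared genotype-dosage correlation as an unphased fallback. Pairs
#' monomorphic on their shared non-missing set are skipped. When the number
#' of eligible pairs exceeds `max_pairs` a seeded uniform subsample is taken
#' (draws come from the caller's RNG stream).
#'
#' @param gm a [genotype_matrix()].
#' @param max_dist maximum pair distance in bp (must be positive).
#' @param use_phase use true haplotypes (default when phased).
#' @param max_pairs subsampling cap on the number of pairs.
#' @return data.frame with `scaffold`, `pos1`, `pos2`, `dist`, `r2`, and an
#'   attribute `n_pairs_total` (eligible pairs before subsampling).
#' @export
pairwise_r2 <- function(gm, max_dist, use_phase = gm$phased,
                        max_pairs = 1e6) {
  if (max_dist <= 0) stop("max_dist must be positive")
  X <- if (use_phase) haplotypes(gm) else t(geno_dosage(gm))
  # orient as units x sites
  if (use_phase) X <- t(X)
  ii_l <- list(); jj_l <- list()
  for (sc in unique(gm$sites$scaffold)) {
    sel <- which(gm$sites$scaffold == sc)
    sel <- sel[order(gm$sites$pos[sel])]
    pos <- gm$sites$pos[sel]
    if (length(sel) < 2) next
    hi <- findInterval(pos + max_dist, pos)
    cnt <- pmax(hi - seq_along(pos), 0L)
    if (sum(cnt) == 0) next
    k <- length(ii_l) + 1L
    ii_l[[k]] <- sel[rep(seq_along(pos), cnt)]
    jj_l[[k]] <- sel[sequence(cnt, from = seq_along(pos) + 1L)]
  }
  ii <- unlist(ii_l, use.names = FALSE)
  jj <- unlist(jj_l, use.names = FALSE)
  n_total <- length(ii)
  if (is.null(ii)) ii <- jj <- integer(0)
  if (n_total > max_pairs) {
    take <- sort(sample.int(n_total, max_pairs))
    ii <- ii[take]; jj <- jj[take]
  }
  scv <- gm$sites$scaffold[ii]
  r2 <- numeric(length(ii))
  chunk <- 50000L
  for (s in seq(1L, length(ii), by = chunk)) {
    e <- min(s + chunk - 1L, length(ii))
    A <- X[, ii[s:e], drop = FALSE]
    B <- X[, jj[s:e], drop = FALSE]
    ok <- !is.na(A) & !is.na(B)
    A[!ok] <- 0; B[!ok] <- 0
    nob <- colSums(ok)
    sA <- colSums(A); sB <- colSums(B)
    sAB <- colSums(A * B)
    if (use_phase) {
      pA <- sA / nob; pB <- sB / nob
      D <- sAB / nob - pA * pB
      den <- pA * (1 - pA) * pB * (1 - pB)
      r2[s:e] <- ifelse(nob > 0 & den > 0, D * D / den, NA_real_)
    } else {
      sAA <- colSums(A * A); sBB <- colSums(B * B)
      covAB <- sAB - sA * sB / nob
      vA <- sAA - sA^2 / nob; vB <- sBB - sB^2 / nob
      r2[s:e] <- ifelse(nob > 1 & vA > 0 & vB > 0,
                        (covAB * covAB) / (vA * vB), NA_real_)
    }
  }
  keep <- !is.na(r2)
  res <- data.frame(scaffold = scv[keep],
                    pos1 = gm$sites$pos[ii[keep]],
                    pos2 = gm$sites$pos[jj[keep]],
                    dist = gm$sites$pos[jj[keep]] - gm$sites$pos[ii[keep]],
                    r2 = r2[keep])
  attr(res, "n_pairs_total") <- n_total
  res
}

#' LD decay curve and half-maximum distance
#'
#' Bins pairwise r-squared by distance, averages per bin, and locates the
#' distance at which mean r-squared first falls to half of its maximum
#' binned value, scanning outward from the maximum bin with linear
#' interpolation between the flanking bin centers. Curves that never reach
#' half maximum (or have a single bin) leave `half_max_distance` undefined
#' and flagged.
#'
#' @param pairs output of [pairwise_r2()] (or any data.frame with `dist`
#'   and `r2`).
#' @param bin_width distance bin width in bp (default 5 kb).
#' @return A list of class `ld_decay`: `curve` (data.frame `bin_start`,
#'   `bin_end`, `bin_mid`, `n_pairs`, `mean_r2`), `max_r2`,
#'   `half_max_distance` and `flagged`.
#' @export
decay_curve <- function(pairs, bin_width = 5000L) {
  if (nrow(pairs) == 0) stop("no pairs to bin")
  bin <- pmax(ceiling(pairs$dist / bin_width), 1L)
  agg <- tapply(pairs$r2, bin, mean)
  cnt <- tapply(pairs$r2, bin, length)
  b <- as.integer(names(agg))
  curve <- data.frame(bin_start = (b - 1L) * bin_width,
                      bin_end = b * bin_width,
                      bin_mid = (b - 0.5) * bin_width,
                      n_pairs = as.integer(cnt),
                      mean_r2 = as.numeric(agg))
  curve <- curve[order(curve$bin_mid), ]
  rownames(curve) <- NULL
  imax <- which.max(curve$mean_r2)
  max_r2 <- curve$mean_r2[imax]
  half <- max_r2 / 2
  half_dist <- NA_real_
  flagged <- TRUE
  if (nrow(curve) > imax) {
    below <- which(curve$mean_r2[(imax + 1L):nrow(curve)] <= half)
    if (length(below) > 0) {
      k <- imax + below[1]
      x1 <- curve$bin_mid[k - 1L]; y1 <- curve$mean_r2[k - 1L]
      x2 <- curve$bin_mid[k]; y2 <- curve$mean_r2[k]
      half_dist <- if (y1 == y2) x2 else x1 + (y1 - half) / (y1 - y2) * (x2 - x1)
      flagged <- FALSE
    }
  }
  structure(list(curve = curve, max_r2 = max_r2,
                 half_max_distance = half_dist, flagged = flagged),
            class = "ld_decay")
}

#' @export
print.ld_decay <- function(x, ...) {
  cat(sprintf("ld_decay: %d bins, max r2 = %.3f, half-max distance = %s\n",
              nrow(x$curve), x$max_r2,
              if (x$flagged) "undefined" else format(round(x$half_max_distance))))
  invisible(x)
}

#' One-call LD decay analysis
#'
#' @inheritParams pairwise_r2
#' @inheritParams decay_curve
#' @return An `ld_decay` object (see [decay_curve()]).
#' @export
ld_decay <- function(gm, max_dist = 250000L, bin_width = 5000L,
                     use_phase = gm$phased, max_pairs = 1e6) {
  decay_curve(pairwise_r2(gm, max_dist, use_phase, max_pairs), bin_width)
}
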
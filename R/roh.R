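#' Call runs of homozygosity for one individual
#'
#' Sliding-window heterozygote-density caller over the individual's
#' genotyped sites: every run of `window_sites` consecutive genotyped sites
#' containing at most `max_het` heterozygotes seeds a candidate region;
#' overlapping passing windows are merged, merged regions are trimmed to
#' their outermost homozygous genotyped sites, and regions supported by
#' fewer than `min_snv` genotyped sites are dropped. Segments never span
#' scaffold boundaries. Coordinates are 0-based half-open.
#'
#' @param gm a [genotype_matrix()].
#' @param individual sample name.
#' @param window_sites sites per window (default 50).
#' @param max_het maximum heterozygotes per window (default 1).
#' @param min_snv minimum genotyped sites supporting a segment (default 25).
#' @return data.frame with `individual`, `scaffold`, `start`, `end`,
#'   `length`, `n_hets`, `n_genotyped`.
#' @export
call_roh <- function(gm, individual, window_sites = 50L, max_het = 1L,
                     min_snv = 25L) {
  j <- match(individual, gm$samples)
  if (is.na(j)) stop("unknown individual: ", individual)
  het_all <- geno_is_het(gm)[, j]
  miss_all <- geno_is_missing(gm)[, j]
  segs <- list()
  for (sc in unique(gm$sites$scaffold)) {
    sel <- which(gm$sites$scaffold == sc & !miss_all)
    sel <- sel[order(gm$sites$pos[sel])]
    if (length(sel) < min_snv) next
    pos <- gm$sites$pos[sel]
    het <- as.integer(het_all[sel])
    m <- length(sel)
    w <- min(window_sites, m)
    ch <- cumsum(c(0L, het))
    nwin <- m - w + 1L
    win_het <- ch[(w + 1L):(w + nwin)] - ch[seq_len(nwin)]
    pass <- win_het <= max_het
    if (!any(pass)) next
    covered <- logical(m)
    for (k in which(pass)) covered[k:(k + w - 1L)] <- TRUE
    r <- rle(covered)
    ends_i <- cumsum(r$lengths)
    starts_i <- ends_i - r$lengths + 1L
    for (b in which(r$values)) {
      i0 <- starts_i[b]; i1 <- ends_i[b]
      hom_in <- which(het[i0:i1] == 0L)
      if (length(hom_in) == 0) next
      i0t <- i0 + hom_in[1] - 1L
      i1t <- i0 + hom_in[length(hom_in)] - 1L
      n_gt <- i1t - i0t + 1L
      if (n_gt < min_snv) next
      segs[[length(segs) + 1L]] <- data.frame(
        individual = individual, scaffold = sc,
        start = pos[i0t] - 1L, end = pos[i1t],
        length = pos[i1t] - pos[i0t] + 1L,
        n_hets = sum(het[i0t:i1t]), n_genotyped = n_gt)
    }
  }
  if (length(segs) == 0)
    return(data.frame(individual = character(0), scaffold = character(0),
                      start = integer(0), end = integer(0),
                      length = integer(0), n_hets = integer(0),
                      n_genotyped = integer(0)))
  res <- do.call(rbind, segs)
  rownames(res) <- NULL
  res
}

#' FROH: fraction of the genome in long runs of homozygosity
#'
#' Sum of ROH segment lengths strictly greater than `min_segment` (default
#' 100 kb) divided by the genome's effective length (the QC-accessible
#' length, kept consistent with the accessibility convention of the
#' diversity statistics).
#'
#' @param segments output of [call_roh()] (one individual).
#' @param effective_length genome effective length in bp.
#' @param min_segment length floor in bp; segments must exceed it strictly.
#' @return A one-row data.frame: `individual`, `froh`, `n_segments`,
#'   `roh_bp`, `min_segment_bp`, `effective_length`.
#' @export
froh <- function(segments, effective_length, min_segment = 100000L) {
  if (effective_length <= 0) stop("effective_length must be positive")
  keep <- segments$length > min_segment
  roh_bp <- sum(as.numeric(segments$length[keep]))
  data.frame(individual = if (nrow(segments)) segments$individual[1]
             else NA_character_,
             froh = roh_bp / effective_length,
             n_segments = sum(keep), roh_bp = roh_bp,
             min_segment_bp = min_segment,
             effective_length = effective_length)
}

#' FROH for every individual
#'
#' @param gm a [genotype_matrix()].
#' @param effective_length genome effective length in bp.
#' @param ... passed to [call_roh()] and [froh()].
#' @inheritParams froh
#' @return data.frame with one row per individual.
#' @export
froh_all <- function(gm, effective_length, min_segment = 100000L, ...) {
  rows <- lapply(gm$samples, function(ind) {
    f <- froh(call_roh(gm, ind, ...), effective_length, min_segment)
    f$individual <- ind
    f
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
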
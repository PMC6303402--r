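# Degeneracy label of one codon position under a given rule, from the
# standard genetic code. Variants creating stop codons count as a distinct
# 21st amino-acid state.
.degeneracy_env <- new.env(parent = emptyenv())

codon_position_degeneracy <- function(rule = c("paper", "conventional")) {
  rule <- match.arg(rule)
  key <- paste0("tab_", rule)
  if (!is.null(.degeneracy_env[[key]])) return(.degeneracy_env[[key]])
  gc_tab <- Biostrings::GENETIC_CODE
  bases <- c("A", "C", "G", "T")
  codons <- names(gc_tab)
  tab <- matrix("other", length(codons), 3L,
                dimnames = list(codons, NULL))
  for (cd in codons) {
    for (k in 1:3) {
      vars <- vapply(bases, function(b) {
        v <- cd
        substr(v, k, k) <- b
        unname(gc_tab[v])
      }, character(1))
      ref_aa <- unname(gc_tab[cd])
      lab <- if (length(unique(vars)) == 1L) "four_fold"
      else if (rule == "paper" && length(unique(vars)) == 4L) "zero_fold"
      else if (rule == "conventional" &&
               all(vars[bases != substr(cd, k, k)] != ref_aa)) "zero_fold"
      else "other"
      tab[cd, k] <- lab
    }
  }
  .degeneracy_env[[key]] <- tab
  tab
}

#' Classify CDS sites by codon degeneracy
#'
#' For every CDS position, substitutes all four bases in its codon and
#' translates with the standard genetic code. Under the default `"paper"`
#' rule a site is `zero_fold` only when the four substitutions yield four
#' pairwise distinct amino acids, and `four_fold` when they yield one;
#' everything else is `other`. The `"conventional"` rule instead calls
#' `zero_fold` whenever every base change alters the amino acid (e.g. the
#' first position of ATG, where two alternatives both give Leu, is
#' conventional zero-fold but `other` under the strict rule). Stop codons
#' arising from substitution count as a distinct amino-acid state.
#'
#' Minus-strand CDS are reverse-complemented before codon iteration; exon
#' phase trims incomplete leading codons. Genes whose spliced CDS is not a
#' multiple of 3 or contains an internal stop are skipped with a warning,
#' and sites covered by CDS of more than one gene are excluded.
#'
#' @param reference a [Biostrings::DNAStringSet].
#' @param genes CDS exon data.frame (see [generate_genome()]).
#' @param rule `"paper"` (strict) or `"conventional"`.
#' @return data.frame with `scaffold`, `pos` (1-based), `strand`, `gene_id`,
#'   `codon`, `codon_pos` (1-3) and `label`.
#' @export
classify_degeneracy <- function(reference, genes,
                                rule = c("paper", "conventional")) {
  rule <- match.arg(rule)
  tab <- codon_position_degeneracy(rule)
  gc_tab <- Biostrings::GENETIC_CODE
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  # one flat character vector per scaffold avoids per-gene S4 dispatch
  ref_chars <- lapply(as.character(reference), function(s)
    strsplit(s, "", fixed = TRUE)[[1]])
  out <- list()
  for (gid in unique(genes$gene_id)) {
    g <- genes[genes$gene_id == gid, , drop = FALSE]
    g <- g[order(g$exon_rank), , drop = FALSE]
    sc <- g$scaffold[1]
    chars <- vector("list", nrow(g))
    coords <- vector("list", nrow(g))
    for (e in seq_len(nrow(g))) {
      v <- ref_chars[[sc]][g$start[e]:g$end[e]]
      if (g$strand[1] == "-") {
        chars[[e]] <- unname(comp[rev(v)])
        coords[[e]] <- seq(g$end[e], g$start[e])
      } else {
        chars[[e]] <- v
        coords[[e]] <- seq(g$start[e], g$end[e])
      }
    }
    cds <- unlist(chars, use.names = FALSE)
    pos_t <- unlist(coords, use.names = FALSE)
    ph <- g$phase[1]
    if (ph > 0) {
      cds <- cds[-seq_len(ph)]
      pos_t <- pos_t[-seq_len(ph)]
    }
    if (length(cds) %% 3L != 0L) {
      warning("gene ", gid, " skipped: CDS length not a multiple of 3")
      next
    }
    n_cod <- length(cds) / 3L
    cod_mat <- matrix(cds, nrow = 3L)
    codons_u <- paste0(cod_mat[1, ], cod_mat[2, ], cod_mat[3, ])
    aa_vec <- unname(gc_tab[codons_u])
    if (any(is.na(aa_vec)) || any(aa_vec[-n_cod] == "*")) {
      warning("gene ", gid, " skipped: internal stop codon")
      next
    }
    codons <- rep(codons_u, each = 3L)
    offs <- rep(1:3, n_cod)
    labs <- tab[cbind(match(codons, rownames(tab)), offs)]
    out[[gid]] <- list(scaffold = rep(sc, length(pos_t)), pos = pos_t,
                       strand = rep(g$strand[1], length(pos_t)),
                       gene_id = rep(gid, length(pos_t)),
                       codon = codons, codon_pos = offs, label = labs)
  }
  if (length(out) == 0)
    return(data.frame(scaffold = character(0), pos = integer(0),
                      strand = character(0), gene_id = character(0),
                      codon = character(0), codon_pos = integer(0),
                      label = character(0)))
  res <- data.frame(
    scaffold = unlist(lapply(out, `[[`, "scaffold"), use.names = FALSE),
    pos = unlist(lapply(out, `[[`, "pos"), use.names = FALSE),
    strand = unlist(lapply(out, `[[`, "strand"), use.names = FALSE),
    gene_id = unlist(lapply(out, `[[`, "gene_id"), use.names = FALSE),
    codon = unlist(lapply(out, `[[`, "codon"), use.names = FALSE),
    codon_pos = unlist(lapply(out, `[[`, "codon_pos"), use.names = FALSE),
    label = unlist(lapply(out, `[[`, "label"), use.names = FALSE),
    stringsAsFactors = FALSE)
  key <- paste(res$scaffold, res$pos)
  dup <- key %in% key[duplicated(key)]
  res <- res[!dup, , drop = FALSE]  # overlapping CDS excluded
  res <- res[order(res$scaffold, res$pos), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Zero-fold to four-fold heterozygosity ratio
#'
#' Per individual: (heterozygotes / genotyped sites) at zero-fold degenerate
#' sites divided by the same quantity at four-fold sites. Sites of the
#' degeneracy map absent from the genotype matrix count as genotyped
#' homozygous-reference; missing genotypes at variant sites are subtracted
#' from the denominators. A zero four-fold heterozygote count leaves the
#' ratio undefined (`NA`, flagged).
#'
#' @param gm a [genotype_matrix()].
#' @param dmap output of [classify_degeneracy()].
#' @return data.frame with per-individual counts, `ratio` and `flagged`.
#' @export
zero_four_ratio <- function(gm, dmap) {
  key_map <- paste(dmap$scaffold, dmap$pos)
  key_gm <- paste(gm$sites$scaffold, gm$sites$pos)
  idx <- match(key_gm, key_map)
  lab_gm <- ifelse(is.na(idx), NA_character_, dmap$label[idx])
  n_zero_tot <- sum(dmap$label == "zero_fold")
  n_four_tot <- sum(dmap$label == "four_fold")
  het <- geno_is_het(gm)
  miss <- geno_is_missing(gm)
  in_zero <- !is.na(lab_gm) & lab_gm == "zero_fold"
  in_four <- !is.na(lab_gm) & lab_gm == "four_fold"
  rows <- lapply(seq_along(gm$samples), function(j) {
    hz <- sum(het[in_zero, j], na.rm = TRUE)
    hf <- sum(het[in_four, j], na.rm = TRUE)
    nz <- n_zero_tot - sum(miss[in_zero, j])
    nf <- n_four_tot - sum(miss[in_four, j])
    rate_z <- if (nz > 0) hz / nz else NA_real_
    rate_f <- if (nf > 0) hf / nf else NA_real_
    undef <- is.na(rate_f) || rate_f == 0 || is.na(rate_z)
    data.frame(individual = gm$samples[j], het_zero = hz, n_zero = nz,
               het_four = hf, n_four = nf,
               ratio = if (undef) NA_real_ else rate_z / rate_f,
               flagged = undef)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
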
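#' Genome template for the simulator
#'
#' Describes the synthetic genome the forward simulator evolves: equal-length
#' scaffolds carrying non-overlapping protein-coding gene models on both
#' strands. Coding sequences are generated without internal stop codons and
#' with total CDS length a multiple of 3; individual exon lengths need not be,
#' so GFF3 phase handling is exercised downstream.
#'
#' @param n_scaffolds number of scaffolds.
#' @param scaffold_length length of each scaffold in bp.
#' @param gene_density genes per 100 kb.
#' @param cds_exons_per_gene integer range (min, max) of CDS exons per gene.
#' @param exon_bp range of exon lengths in bp.
#' @param intron_bp range of intron lengths in bp.
#' @return An object of class `genome_template`.
#' @export
genome_template <- function(n_scaffolds = 4L, scaffold_length = 500000L,
                            gene_density = 25, cds_exons_per_gene = c(2L, 5L),
                            exon_bp = c(120L, 300L), intron_bp = c(80L, 400L)) {
  stopifnot(n_scaffolds >= 1, scaffold_length >= 1000,
            gene_density >= 0, length(cds_exons_per_gene) == 2,
            cds_exons_per_gene[1] >= 1)
  structure(list(n_scaffolds = as.integer(n_scaffolds),
                 scaffold_length = as.integer(scaffold_length),
                 gene_density = gene_density,
                 cds_exons_per_gene = as.integer(cds_exons_per_gene),
                 exon_bp = as.integer(exon_bp),
                 intron_bp = as.integer(intron_bp)),
            class = "genome_template")
}

scaffold_names <- function(template) {
  paste0("scaffold_", seq_len(template$n_scaffolds))
}

# Sense codons (no TAA/TAG/TGA), used to build stop-free CDS.
sense_codons <- function() {
  codons <- names(Biostrings::GENETIC_CODE)
  codons[Biostrings::GENETIC_CODE != "*"]
}

#' Instantiate a genome from a template
#'
#' Draws a random reference sequence and gene models using the current RNG
#' state (call `set.seed()` first for reproducibility). Gene coding sequences
#' are stop-free sense-codon strings beginning with ATG and ending in a stop
#' codon; they are written into the reference on the gene's strand.
#'
#' @param template a [genome_template()].
#' @return A list with `reference` (a [Biostrings::DNAStringSet]) and `genes`,
#'   a data.frame of CDS exons with columns `gene_id`, `scaffold`, `start`,
#'   `end` (1-based inclusive), `strand`, `phase`, `exon_rank`.
#' @export
generate_genome <- function(template) {
  stopifnot(inherits(template, "genome_template"))
  L <- template$scaffold_length
  bases <- c("A", "C", "G", "T")
  sense <- sense_codons()
  stops <- c("TAA", "TAG", "TGA")
  seqs <- character(template$n_scaffolds)
  gene_rows <- list()
  gid <- 0L
  for (sc in seq_len(template$n_scaffolds)) {
    chars <- sample(bases, L, replace = TRUE)
    n_genes <- round(template$gene_density * L / 1e5)
    # walk along the scaffold leaving random intergenic gaps
    cursor <- 1L + sample.int(2000L, 1L)
    for (g in seq_len(max(0L, n_genes))) {
      n_ex <- sample(seq(template$cds_exons_per_gene[1],
                         template$cds_exons_per_gene[2]), 1L)
      ex_len <- sample(seq(template$exon_bp[1], template$exon_bp[2]), n_ex,
                       replace = TRUE)
      cds_len <- sum(ex_len)
      adj <- (3L - cds_len %% 3L) %% 3L
      ex_len[n_ex] <- ex_len[n_ex] + adj
      cds_len <- cds_len + adj
      in_len <- if (n_ex > 1L)
        sample(seq(template$intron_bp[1], template$intron_bp[2]), n_ex - 1L,
               replace = TRUE) else integer(0)
      span <- cds_len + sum(in_len)
      if (cursor + span - 1L > L - 100L) break
      gid <- gid + 1L
      strand <- if (stats::runif(1) < 0.5) "+" else "-"
      cds <- paste0("ATG",
                    paste(sample(sense, cds_len / 3L - 2L, replace = TRUE),
                          collapse = ""),
                    sample(stops, 1L))
      # exon genomic intervals, left to right
      starts <- integer(n_ex); ends <- integer(n_ex)
      p <- cursor
      for (e in seq_len(n_ex)) {
        starts[e] <- p
        ends[e] <- p + ex_len[e] - 1L
        p <- ends[e] + 1L + if (e < n_ex) in_len[e] else 0L
      }
      # write CDS into the scaffold in translation order
      cds_chars <- strsplit(cds, "")[[1]]
      if (strand == "-")
        cds_chars <- rev(c(A = "T", C = "G", G = "C", T = "A")[cds_chars])
      # genomic left-to-right concatenation of exons spells the CDS (+) or its
      # reverse complement (-); either way fill exons left to right
      off <- 0L
      for (e in seq_len(n_ex)) {
        chars[starts[e]:ends[e]] <- cds_chars[(off + 1L):(off + ex_len[e])]
        off <- off + ex_len[e]
      }
      # translation-order exon ranks and phases
      ord <- if (strand == "+") seq_len(n_ex) else rev(seq_len(n_ex))
      cum <- cumsum(c(0L, ex_len[ord][-n_ex]))
      phase <- (3L - cum %% 3L) %% 3L
      gene_rows[[gid]] <- data.frame(
        gene_id = sprintf("g%04d", gid),
        scaffold = scaffold_names(template)[sc],
        start = starts, end = ends, strand = strand,
        phase = phase[match(seq_len(n_ex), ord)],
        exon_rank = match(seq_len(n_ex), ord),
        stringsAsFactors = FALSE)
      cursor <- p + sample.int(max(10L, round(1e5 / max(template$gene_density, 1)) ), 1L)
    }
    seqs[sc] <- paste(chars, collapse = "")
  }
  reference <- Biostrings::DNAStringSet(seqs)
  names(reference) <- scaffold_names(template)
  genes <- if (gid > 0L) do.call(rbind, gene_rows) else
    data.frame(gene_id = character(), scaffold = character(),
               start = integer(), end = integer(), strand = character(),
               phase = integer(), exon_rank = integer())
  rownames(genes) <- NULL
  list(reference = reference, genes = genes)
}

#' Partition a genome into region classes
#'
#' Classifies every base as `coding` (inside a CDS), `intron` (inside a gene
#' span but not CDS; untranslated flanks within the span count here too),
#' `near_gene` (within `buffer` bp of a coding base but not genic), or
#' `intergenic` (everything else, i.e. at least `buffer` bp from any coding
#' base). Intervals are returned 1-based inclusive and partition each
#' scaffold.
#'
#' @param genes CDS exon data.frame as from [generate_genome()].
#' @param scaffold_lengths named integer vector of scaffold lengths.
#' @param buffer distance in bp defining `near_gene` (default 10 kb).
#' @return data.frame with `scaffold`, `start`, `end`, `class`.
#' @export
region_class_map <- function(genes, scaffold_lengths, buffer = 10000L) {
  stopifnot(!is.null(names(scaffold_lengths)))
  out <- list()
  for (sc in names(scaffold_lengths)) {
    L <- scaffold_lengths[[sc]]
    all_ir <- IRanges::IRanges(1L, L)
    g <- genes[genes$scaffold == sc, , drop = FALSE]
    if (nrow(g) == 0) {
      out[[sc]] <- data.frame(scaffold = sc, start = 1L, end = L,
                              class = "intergenic")
      next
    }
    cds <- IRanges::reduce(IRanges::IRanges(g$start, g$end))
    span_lo <- tapply(g$start, g$gene_id, min)
    span_hi <- tapply(g$end, g$gene_id, max)
    span <- IRanges::reduce(IRanges::IRanges(as.integer(span_lo),
                                             as.integer(span_hi)))
    intron <- IRanges::setdiff(span, cds)
    near <- IRanges::restrict(
      IRanges::reduce(IRanges::IRanges(IRanges::start(cds) - buffer,
                                       IRanges::end(cds) + buffer)),
      1L, L)
    near <- IRanges::setdiff(IRanges::setdiff(near, cds), intron)
    inter <- IRanges::setdiff(IRanges::setdiff(
      IRanges::setdiff(all_ir, cds), intron), near)
    piece <- function(ir, cls) {
      if (length(ir) == 0) return(NULL)
      data.frame(scaffold = sc, start = IRanges::start(ir),
                 end = IRanges::end(ir), class = cls)
    }
    out[[sc]] <- rbind(piece(cds, "coding"), piece(intron, "intron"),
                       piece(near, "near_gene"), piece(inter, "intergenic"))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$scaffold, res$start), ]
  rownames(res) <- NULL
  res
}

#' Total length per region class
#'
#' @param map output of [region_class_map()].
#' @return Named numeric vector of bp per class.
#' @export
region_class_lengths <- function(map) {
  vapply(split(map$end - map$start + 1, map$class), sum, numeric(1))
}

#' Locate positions in a region map
#'
#' @param map output of [region_class_map()].
#' @param scaffold,pos vectors of coordinates (1-based).
#' @return Character vector of region classes (`NA` outside the map).
#' @export
region_lookup <- function(map, scaffold, pos) {
  res <- rep(NA_character_, length(pos))
  for (sc in unique(scaffold)) {
    m <- map[map$scaffold == sc, , drop = FALSE]
    if (nrow(m) == 0) next
    sel <- scaffold == sc
    idx <- findInterval(pos[sel], m$start)
    ok <- idx >= 1 & pos[sel] <= m$end[pmax(idx, 1L)]
    res[sel][ok] <- m$class[idx[ok]]
  }
  res
}
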
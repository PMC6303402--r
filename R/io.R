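#' Read and write FASTA references
#'
#' Thin wrappers over Biostrings with 60-column wrapping on output.
#'
#' @param x a [Biostrings::DNAStringSet].
#' @param path file path.
#' @return `read_fasta` returns a `DNAStringSet`.
#' @export
write_fasta <- function(x, path) {
  Biostrings::writeXStringSet(x, path, width = 60L)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) Biostrings::readDNAStringSet(path)

#' Write gene models to GFF3
#'
#' Emits gene / mRNA / CDS features (1-based inclusive, CDS with phase) for a
#' CDS-exon table as produced by [generate_genome()].
#'
#' @param genes CDS exon data.frame (`gene_id`, `scaffold`, `start`, `end`,
#'   `strand`, `phase`, `exon_rank`).
#' @param path output path.
#' @param scaffold_lengths named vector for `##sequence-region` headers.
#' @export
write_gff3 <- function(genes, path, scaffold_lengths = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (!is.null(scaffold_lengths))
    writeLines(sprintf("##sequence-region %s 1 %d", names(scaffold_lengths),
                       as.integer(scaffold_lengths)), con)
  if (nrow(genes) > 0) {
    rows <- character(0)
    for (gid in unique(genes$gene_id)) {
      g <- genes[genes$gene_id == gid, , drop = FALSE]
      g <- g[order(g$start), , drop = FALSE]
      lo <- min(g$start); hi <- max(g$end)
      rows <- c(rows,
        sprintf("%s\terosionkit\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                g$scaffold[1], lo, hi, g$strand[1], gid),
        sprintf("%s\terosionkit\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s.t1;Parent=%s",
                g$scaffold[1], lo, hi, g$strand[1], gid, gid),
        sprintf("%s\terosionkit\tCDS\t%d\t%d\t.\t%s\t%d\tID=%s.t1.cds;Parent=%s.t1",
                g$scaffold, g$start, g$end, g$strand, g$phase, gid, gid))
    }
    writeLines(rows, con)
  }
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Imports CDS features (via rtracklayer) and reconstructs the CDS-exon
#' table; genes are identified by the CDS `Parent` attribute with a trailing
#' transcript suffix (`.t1`) stripped when present.
#'
#' @param path GFF3 file.
#' @return CDS exon data.frame as in [generate_genome()].
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path)
  cds <- gr[gr$type == "CDS"]
  if (length(cds) == 0)
    return(data.frame(gene_id = character(), scaffold = character(),
                      start = integer(), end = integer(),
                      strand = character(), phase = integer(),
                      exon_rank = integer()))
  parent <- vapply(as.list(cds$Parent), function(p)
    if (length(p)) p[[1]] else NA_character_, character(1))
  gene_id <- sub("\\.t[0-9]+$", "", parent)
  df <- data.frame(gene_id = gene_id,
                   scaffold = as.character(GenomicRanges::seqnames(cds)),
                   start = GenomicRanges::start(cds),
                   end = GenomicRanges::end(cds),
                   strand = as.character(GenomicRanges::strand(cds)),
                   phase = as.integer(cds$phase),
                   stringsAsFactors = FALSE)
  df <- df[order(df$gene_id, df$start), , drop = FALSE]
  rank1 <- stats::ave(df$start, df$gene_id, FUN = seq_along)
  nex <- stats::ave(df$start, df$gene_id, FUN = length)
  df$exon_rank <- ifelse(df$strand == "+", rank1, nex - rank1 + 1)
  df$exon_rank <- as.integer(df$exon_rank)
  rownames(df) <- NULL
  df
}

#' Write genotypes to VCF v4.2
#'
#' Writes GT (phased with `|` when the matrix is phased), GQ and DP. Missing
#' genotypes become `./.`.
#'
#' @param gm a [genotype_matrix()] (or `variant_set`).
#' @param path output path.
#' @param scaffold_lengths optional named vector for `##contig` headers.
#' @export
write_vcf <- function(gm, path, scaffold_lengths = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  hdr <- c("##fileformat=VCFv4.2",
           "##source=erosionkit",
           if (!is.null(scaffold_lengths))
             sprintf("##contig=<ID=%s,length=%d>", names(scaffold_lengths),
                     as.integer(scaffold_lengths)),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype Quality\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read Depth\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", gm$samples), collapse = "\t"))
  writeLines(hdr, con)
  m <- nrow(gm$sites)
  if (m > 0) {
    sep <- if (gm$phased) "|" else "/"
    gt <- matrix(paste(ifelse(is.na(gm$a1), ".", gm$a1), sep,
                       ifelse(is.na(gm$a2), ".", gm$a2), sep = ""),
                 m, length(gm$samples))
    gt[is.na(gm$a1) | is.na(gm$a2)] <- "./."
    gq <- if (!is.null(gm$gq)) gm$gq else matrix(99L, m, length(gm$samples))
    dp <- if (!is.null(gm$dp)) gm$dp else matrix(0L, m, length(gm$samples))
    fld <- matrix(paste(gt, gq, dp, sep = ":"), m, length(gm$samples))
    lines <- paste(gm$sites$scaffold, gm$sites$pos, ".", gm$sites$ref,
                   gm$sites$alt, ".", "PASS", ".", "GT:GQ:DP",
                   apply(fld, 1, paste, collapse = "\t"), sep = "\t")
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read a VCF into a variant_set
#'
#' Parses an uncompressed or gzipped VCF (via vcfR) into a [variant_set()]:
#' multiallelic records and indels are retained for the QC cascade to handle.
#'
#' @param path VCF file.
#' @return A [variant_set()].
#' @export
read_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(nrow(fix))) fix <- matrix(fix, nrow = 1,
                                        dimnames = list(NULL, names(fix)))
  m <- nrow(vcf@gt) # 0 when header-only
  samples <- colnames(vcf@gt)[-1]
  if (is.null(samples)) samples <- character(0)
  if (m == 0 || nrow(fix) == 0) {
    z <- matrix(integer(0), 0, length(samples),
                dimnames = list(NULL, samples))
    return(variant_set(data.frame(scaffold = character(0), pos = integer(0),
                                  ref = character(0), alt = character(0),
                                  is_indel = logical(0)),
                       z, z, gq = z, dp = z, samples = samples))
  }
  gt <- vcfR::extract.gt(vcf, "GT")
  gq <- suppressWarnings(vcfR::extract.gt(vcf, "GQ", as.numeric = TRUE))
  dp <- suppressWarnings(vcfR::extract.gt(vcf, "DP", as.numeric = TRUE))
  phased <- any(grepl("|", gt, fixed = TRUE), na.rm = TRUE)
  a1 <- suppressWarnings(matrix(as.integer(sub("^([0-9.]+)[/|].*$", "\\1",
                                               gt)), m))
  a2 <- suppressWarnings(matrix(as.integer(sub("^.*[/|]([0-9.]+)$", "\\1",
                                               gt)), m))
  colnames(a1) <- colnames(a2) <- samples
  sites <- data.frame(scaffold = fix[, "CHROM"],
                      pos = as.integer(fix[, "POS"]),
                      ref = fix[, "REF"], alt = fix[, "ALT"],
                      stringsAsFactors = FALSE)
  variant_set(sites, a1, a2,
              gq = matrix(as.integer(gq), m, dimnames = dimnames(a1)),
              dp = matrix(as.integer(dp), m, dimnames = dimnames(a1)),
              samples = samples, phased = phased)
}

#' Write a simulated dataset to disk
#'
#' Writes reference FASTA, gene GFF3, sample and outgroup VCFs, the truth
#' table TSV and (if `effects` is given) a predictor-call TSV, plus a
#' manifest.
#'
#' @param ds a `simulated_dataset` from [simulate_two_populations()].
#' @param outdir output directory (created if needed).
#' @param effects optional effect-call table from [simulate_effect_calls()].
#' @return Invisibly, a manifest data.frame (`file`, `path`, `md5`).
#' @export
write_dataset <- function(ds, outdir, effects = NULL) {
  stopifnot(inherits(ds, "simulated_dataset"))
  if (!dir.exists(outdir) &&
      !dir.create(outdir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", outdir)
  lens <- setNames(Biostrings::width(ds$reference), names(ds$reference))
  paths <- c(reference = file.path(outdir, "reference.fa"),
             genes = file.path(outdir, "genes.gff3"),
             genotypes = file.path(outdir, "genotypes.vcf"),
             outgroups = file.path(outdir, "outgroups.vcf"),
             truth = file.path(outdir, "truth.tsv"))
  write_fasta(ds$reference, paths["reference"])
  write_gff3(ds$genes, paths["genes"], lens)
  write_vcf(ds$gm, paths["genotypes"], lens)
  write_vcf(ds$outgroups, paths["outgroups"], lens)
  write.table(ds$truth, paths["truth"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(effects)) {
    paths <- c(paths, effects = file.path(outdir, "effects.tsv"))
    write.table(effects, paths["effects"], sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  manifest <- data.frame(file = names(paths), path = unname(paths),
                         md5 = unname(tools::md5sum(unname(paths))))
  write.table(manifest, file.path(outdir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(manifest)
}

#' Read a simulated dataset back from disk
#'
#' @param outdir directory written by [write_dataset()].
#' @return A list with `reference`, `genes`, `gm`, `outgroups`, `truth` (and
#'   `effects` when present).
#' @export
read_dataset <- function(outdir) {
  gm <- as_genotype_matrix(read_vcf(file.path(outdir, "genotypes.vcf")))
  og <- as_genotype_matrix(read_vcf(file.path(outdir, "outgroups.vcf")))
  truth <- read.table(file.path(outdir, "truth.tsv"), header = TRUE,
                      sep = "\t", stringsAsFactors = FALSE,
                      colClasses = c(scaffold = "character",
                                     ref = "character", alt = "character",
                                     ancestral = "character",
                                     class = "character"))
  res <- list(reference = read_fasta(file.path(outdir, "reference.fa")),
              genes = read_gff3(file.path(outdir, "genes.gff3")),
              gm = gm, outgroups = og, truth = truth)
  eff_path <- file.path(outdir, "effects.tsv")
  if (file.exists(eff_path))
    res$effects <- read.table(eff_path, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
  res
}
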
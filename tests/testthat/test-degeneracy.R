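# Independent oracle built on seqinr's codon translation.
oracle_site_label <- function(codon, k, rule) {
  bases <- c("a", "c", "g", "t")
  aas <- vapply(bases, function(b) {
    v <- strsplit(tolower(codon), "")[[1]]
    v[k] <- b
    seqinr::translate(v)
  }, character(1))
  ref_aa <- seqinr::translate(strsplit(tolower(codon), "")[[1]])
  if (length(unique(aas)) == 1) return("four_fold")
  if (rule == "paper") {
    if (length(unique(aas)) == 4) "zero_fold" else "other"
  } else {
    alt <- aas[bases != tolower(substr(codon, k, k))]
    if (all(alt != ref_aa)) "zero_fold" else "other"
  }
}

test_that("codon-position labels match the stated examples", {
  skip_if_not_installed("seqinr")
  tab_p <- erosionkit:::codon_position_degeneracy("paper")
  tab_c <- erosionkit:::codon_position_degeneracy("conventional")
  # position 2 of ATG: Lys/Thr/Arg/Met, four distinct -> zero-fold
  expect_equal(unname(tab_p["ATG", 2]), "zero_fold")
  # position 3 of GGA: all Gly -> four-fold
  expect_equal(unname(tab_p["GGA", 3]), "four_fold")
  # position 1 of ATG: Met/Leu/Val/Leu -> strict rule says other,
  # conventional rule (every change alters the amino acid) says zero-fold
  expect_equal(unname(tab_p["ATG", 1]), "other")
  expect_equal(unname(tab_c["ATG", 1]), "zero_fold")
})

test_that("all sense codons match the exhaustive translation oracle", {
  skip_if_not_installed("seqinr")
  sense <- erosionkit:::sense_codons()
  expect_length(sense, 61L)
  for (rule in c("paper", "conventional")) {
    tab <- erosionkit:::codon_position_degeneracy(rule)
    for (cd in sense) {
      for (k in 1:3) {
        expect_equal(unname(tab[cd, k]), oracle_site_label(cd, k, rule),
                     info = paste(rule, cd, k))
      }
    }
  }
})

test_that("genomic classification agrees with per-site re-translation", {
  skip_if_not_installed("seqinr")
  set.seed(5)
  g <- generate_genome(genome_template(1L, 40000L, gene_density = 25))
  dmap <- classify_degeneracy(g$reference, g$genes, rule = "paper")
  expect_gt(nrow(dmap), 1000)
  # four-fold sites only ever sit at codon third positions
  expect_true(all(dmap$codon_pos[dmap$label == "four_fold"] == 3L))
  # spot-exhaustive re-derivation from the codon context the map reports
  for (i in sample(nrow(dmap), 400)) {
    expect_equal(dmap$label[i],
                 oracle_site_label(dmap$codon[i], dmap$codon_pos[i], "paper"))
  }
})

test_that("labels are invariant under reverse complementation of the genome", {
  set.seed(6)
  g <- generate_genome(genome_template(1L, 30000L, gene_density = 20))
  L <- Biostrings::width(g$reference)[1]
  rc <- Biostrings::reverseComplement(g$reference)
  genes_rc <- g$genes
  genes_rc$start <- L - g$genes$end + 1L
  genes_rc$end <- L - g$genes$start + 1L
  genes_rc$strand <- ifelse(g$genes$strand == "+", "-", "+")
  d1 <- classify_degeneracy(g$reference, g$genes)
  d2 <- classify_degeneracy(rc, genes_rc)
  expect_equal(table(d1$label), table(d2$label))
  # site-by-site: position p maps to L - p + 1
  m1 <- setNames(d1$label, d1$pos)
  m2 <- setNames(d2$label, L - d2$pos + 1L)
  expect_equal(m1[order(as.integer(names(m1)))],
               m2[order(as.integer(names(m2)))])
})

test_that("defective gene models are skipped and overlaps excluded", {
  seqs <- Biostrings::DNAStringSet(c(sc = paste(
    c("ATGTGTTGTTAA",              # 1-12: clean gene
      "ATGTAATGTTGA",              # 13-24: internal stop at codon 2
      "ATGTGTTGTTAAG",             # 25-37: length 13, not a multiple of 3
      strrep("A", 30)), collapse = "")))
  genes <- data.frame(
    gene_id = c("ok", "stop", "len"),
    scaffold = "sc",
    start = c(1L, 13L, 25L), end = c(12L, 24L, 37L),
    strand = "+", phase = 0L, exon_rank = 1L)
  expect_warning(expect_warning(
    d <- classify_degeneracy(seqs, genes),
    "internal stop"), "multiple of 3")
  expect_setequal(unique(d$gene_id), "ok")
})

test_that("sites under overlapping CDS of two genes are excluded", {
  seqs <- Biostrings::DNAStringSet(c(sc = "ATGTGCTGCTGCTGCTAA"))
  genes <- data.frame(gene_id = c("g1", "g2"), scaffold = "sc",
                      start = c(1L, 4L), end = c(18L, 15L),
                      strand = "+", phase = 0L, exon_rank = 1L)
  d <- classify_degeneracy(seqs, genes)
  expect_false(any(d$pos %in% 4:15))
  expect_setequal(d$pos, c(1:3, 16:18))
})

test_that("the zero:four-fold heterozygosity ratio follows its definition", {
  dmap <- data.frame(scaffold = "s",
                     pos = 1:2000,
                     strand = "+", gene_id = "g",
                     codon = "NNN", codon_pos = 1L,
                     label = rep(c("zero_fold", "four_fold"), each = 1000))
  # S1: het at 2 zero-fold and 8 four-fold sites -> ratio 0.25
  geno <- matrix("0/0", 10, 2)
  geno[1:2, 1] <- "0/1"              # zero-fold hets (pos 1, 2)
  geno[3:10, 1] <- "0/0"
  gm <- gm_from_strings(geno, pos = c(1:2, 1001:1008), scaffold = "s")
  gm$a2[3:10, 1] <- 1L               # four-fold hets for S1
  z4 <- zero_four_ratio(gm, dmap)
  expect_equal(z4$ratio[1], (2 / 1000) / (8 / 1000))
  # equal het rates in both classes -> ratio 1
  gm2 <- gm_from_strings(matrix("0/1", 2, 1), pos = c(5L, 1005L),
                         scaffold = "s")
  z42 <- zero_four_ratio(gm2, dmap)
  expect_equal(z42$ratio[1], 1)
  # no four-fold heterozygosity -> undefined, flagged
  gm3 <- gm_from_strings(matrix("0/1", 1, 1), pos = 5L, scaffold = "s")
  z43 <- zero_four_ratio(gm3, dmap)
  expect_true(is.na(z43$ratio[1]))
  expect_true(z43$flagged[1])
})

test_that("sustained bottlenecks relax selection and raise the 0:4 ratio", {
  z4 <- z4_battery()
  strong <- vapply(z4, `[[`, numeric(1), "strong")
  relaxed <- vapply(z4, `[[`, numeric(1), "relaxed")
  ok <- !is.na(strong) & !is.na(relaxed)
  expect_gte(mean(relaxed[ok] > strong[ok]), 0.7)
})
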
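# Location classification, coding consequences, census accounting.

# single-gene chromosome with a fully specified CDS:
# pad(10) + CDS 11-22 = ATG GGA TAC TAA + pad to 60
mini_model <- function() {
  genome <- Biostrings::DNAStringSet(c(
    chrM = paste0(strrep("A", 10), "ATGGGATACTAA", strrep("C", 38))))
  gm <- gene_models(
    data.frame(gene_id = "geneM", chrom = "chrM", strand = "+",
               start = 11L, end = 22L),
    data.frame(gene_id = "geneM", chrom = "chrM", strand = "+",
               start = 11L, end = 22L, exon_rank = 1L))
  list(gm = gm, genome = genome)
}

test_that("location classification follows the precedence rules", {
  gm <- toy_gene_models()
  sites <- rbind(
    snp_site("chrT", 150, "A", "G"),   # CDS of geneA -> exonic
    snp_site("chrT", 162, "A", "G"),   # 2 bp into the intron -> splicing
    snp_site("chrT", 180, "A", "G"),   # mid-intron -> intronic
    snp_site("chrT", 80, "A", "G"),    # 21 bp 5' of geneA with small flank
    snp_site("chrT", 700, "A", "G"),   # down of geneA(+) and up of geneB(-)
    snp_site("chrT", 1900, "A", "G"))  # beyond all flanks
  loc <- classify_location(sites, gm, flank = 40, splice_window = 2)
  expect_equal(loc$location[1:4], c("exonic", "splicing", "intronic", "upstream"))
  expect_equal(loc$gene_ids[1:4], c("geneA", "geneA", "geneA", "geneA"))
  loc2 <- classify_location(sites, gm, flank = 1000, splice_window = 2)
  expect_equal(loc2$location[5], "upstream/downstream")
  expect_true(all(c("geneA", "geneB") %in%
                    strsplit(loc2$gene_ids[5], ",")[[1]]))
  expect_equal(loc2$location[6], "intergenic")
  # exonic wins over the other gene's flank regions
  expect_equal(loc2$location[1], "exonic")
  # beyond-chromosome positions are rejected
  expect_error(
    classify_location(snp_site("chrT", 5000, "A", "G"), gm,
                      chrom_lengths = c(chrT = 2000)),
    "beyond chromosome length")
})

test_that("SNP consequences from the standard code, both codon comparisons", {
  mm <- mini_model()
  cases <- rbind(
    cbind(snp_site("chrM", 15, "G", "A"), exp = "nonsynonymous"), # GGA->GAA
    cbind(snp_site("chrM", 16, "A", "G"), exp = "synonymous"),    # GGA->GGG
    cbind(snp_site("chrM", 19, "C", "A"), exp = "stopgain"),      # TAC->TAA
    cbind(snp_site("chrM", 21, "A", "C"), exp = "stoploss"))      # TAA->TCA
  eff <- classify_exonic_effect(cases[names(cases) != "exp"], mm$gm, mm$genome)
  expect_equal(eff, cases$exp)
})

test_that("InDel consequences: frame arithmetic and stop precedence", {
  mm <- mini_model()
  ins3 <- snp_site("chrM", 15, "G", "GTTT")   # in-frame mid-codon insertion
  del2 <- snp_site("chrM", 14, "GGA", "G")    # 2-bp deletion
  ins_stop <- snp_site("chrM", 13, "G", "GTAA") # in-frame insert with stop
  del3 <- snp_site("chrM", 13, "GGGA", "G")   # in-frame 3-bp deletion
  eff <- classify_exonic_effect(rbind(ins3, del2, ins_stop, del3),
                                mm$gm, mm$genome)
  expect_equal(eff, c("non-frameshift insertion", "frameshift deletion",
                      "stopgain", "non-frameshift deletion"))
})

test_that("reference allele mismatches against the genome are hard errors", {
  mm <- mini_model()
  expect_error(
    classify_exonic_effect(snp_site("chrM", 15, "T", "A"), mm$gm, mm$genome),
    "reference allele mismatch")
})

test_that("consequence calls agree with the full-CDS retranslation oracle", {
  withr::local_seed(417)
  gm <- simulate_genes(c(chrZ = 3e5), genes_per_mb = 80)
  genome <- simulate_genome(c(chrZ = 3e5), genes = gm)
  vars <- random_exonic_variants(gm, genome, 300)
  got <- classify_exonic_effect(vars, gm, genome)
  want <- vapply(seq_len(nrow(vars)), function(i)
    oracle_effect(vars[i, ], gm, genome, vars$gene_id[i]), "")
  expect_equal(got, want)
})

test_that("classifications are invariant under reverse-complementing the world", {
  withr::local_seed(91)
  L <- 2e5
  gm <- simulate_genes(c(chrZ = L), genes_per_mb = 60)
  genome <- simulate_genome(c(chrZ = L), genes = gm)
  vars <- random_exonic_variants(gm, genome, 120)

  rc_str <- function(s)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  genome_rc <- Biostrings::DNAStringSet(
    list(chrZ = Biostrings::reverseComplement(genome[[1]])))
  flip <- function(df) {
    ns <- df; ns$start <- L - df$end + 1L; ns$end <- L - df$start + 1L
    ns$strand <- ifelse(df$strand == "+", "-", "+")
    ns
  }
  gm_rc <- gene_models(flip(gm$genes), flip(gm$cds))
  vars_rc <- vars
  for (i in seq_len(nrow(vars))) {
    v <- vars[i, ]
    if (v$vtype == "SNP") {
      vars_rc$pos[i] <- L - v$pos + 1L
      vars_rc$ref[i] <- rc_str(v$ref); vars_rc$alt[i] <- rc_str(v$alt)
    } else if (v$vtype == "deletion") {
      # the base after the deleted run becomes the left anchor under RC
      nd <- nchar(v$ref) - 1L
      vars_rc$pos[i] <- L - v$pos - nd
      vars_rc$ref[i] <- rc_str(as.character(
        Biostrings::subseq(genome[[1]], v$pos + 1L, v$pos + nd + 1L)))
      vars_rc$alt[i] <- substr(vars_rc$ref[i], 1, 1)
    } else {
      b1 <- as.character(Biostrings::subseq(genome[[1]], v$pos + 1L, v$pos + 1L))
      vars_rc$pos[i] <- L - v$pos
      vars_rc$ref[i] <- rc_str(b1)
      vars_rc$alt[i] <- paste0(vars_rc$ref[i],
                               rc_str(substr(v$alt, 2, nchar(v$alt))))
    }
  }
  expect_equal(classify_location(vars_rc, gm_rc)$location,
               classify_location(vars, gm)$location)
  expect_equal(classify_exonic_effect(vars_rc, gm_rc, genome_rc),
               classify_exonic_effect(vars, gm, genome))
})

test_that("census counts partition the variant set and Ts/Tv is correct", {
  gm <- toy_gene_models()
  genome <- toy_genome()
  withr::local_seed(7)
  pos <- sample(setdiff(10:1990, 90:110), 400)
  base <- c("A", "C", "G", "T")
  sites <- do.call(rbind, lapply(pos, function(p) {
    ref <- as.character(Biostrings::subseq(genome[[1]], p, p))
    if (stats::runif(1) < 0.7) snp_site("chrT", p, ref, sample(setdiff(base, ref), 1))
    else snp_site("chrT", p, ref, paste0(ref, sample(base, 1)))
  }))
  ann <- annotate_variants(sites, gm, genome)
  cen <- annotation_census(ann)
  expect_equal(sum(cen$snp$count), cen$total_snp)
  expect_equal(sum(cen$indel$count), cen$total_indel)
  expect_equal(cen$total_snp + cen$total_indel, nrow(sites))
  expect_equal(cen$n_insertion + cen$n_deletion, cen$total_indel)
  expect_equal(cen$ts + cen$tv, cen$total_snp)
  # transition bookkeeping on a fully known set
  known <- rbind(snp_site("chr9", 10, "A", "G"), snp_site("chr9", 20, "C", "T"),
                 snp_site("chr9", 30, "A", "C"))
  known$location <- "intergenic"; known$gene_ids <- ""
  known$exonic_effect <- "none"
  cen2 <- annotation_census(known)
  expect_equal(cen2$ts, 2L)
  expect_equal(cen2$tv, 1L)
  expect_equal(cen2$tstv, 2)
  # a single transition: infinity sentinel
  one <- known[1, ]
  expect_equal(annotation_census(one)$tstv, Inf)
})

test_that("exonic_effect is none exactly for non-exonic variants", {
  gm <- toy_gene_models()
  genome <- toy_genome()
  sites <- rbind(snp_site("chrT", 150, as.character(Biostrings::subseq(genome[[1]], 150, 150)), "A"),
                 snp_site("chrT", 180, "A", "G"),
                 snp_site("chrT", 1900, "A", "G"))
  sites$alt[1] <- setdiff(c("A", "C", "G", "T"), sites$ref[1])[1]
  ann <- annotate_variants(sites, gm, genome)
  expect_equal(ann$exonic_effect != "none", ann$location == "exonic")
})
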
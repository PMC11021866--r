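# Shared fixtures and independent oracles, built in code at test time.

# ---- toy gene models -------------------------------------------------------

# hand-laid two-gene model on one small chromosome:
#   geneA (+): CDS 101-160 and 201-263 (intron 161-200), 60 + 63 = 123 bp
#   geneB (-): CDS 501-560 and 601-663 (intron 561-600), transcribed <-
toy_gene_models <- function() {
  genes <- data.frame(
    gene_id = c("geneA", "geneB"),
    chrom = "chrT", strand = c("+", "-"),
    start = c(101L, 501L), end = c(263L, 663L))
  cds <- data.frame(
    gene_id = c("geneA", "geneA", "geneB", "geneB"),
    chrom = "chrT", strand = c("+", "+", "-", "-"),
    start = c(101L, 201L, 501L, 601L),
    end = c(160L, 263L, 560L, 663L),
    exon_rank = c(1L, 2L, 2L, 1L))
  gene_models(genes, cds)
}

# genome for the toy models: random background, valid ORFs planted
toy_genome <- function(len = 2000, seed = 11) {
  withr::with_seed(seed,
    simulate_genome(c(chrT = len), genes = toy_gene_models()))
}

snp_site <- function(chrom, pos, ref, alt) {
  data.frame(chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
             vtype = ifelse(nchar(ref) == 1 & nchar(alt) == 1, "SNP",
                            ifelse(nchar(alt) > nchar(ref), "insertion",
                                   "deletion")),
             stringsAsFactors = FALSE)
}

# ---- independent full-CDS retranslation oracle -----------------------------

oracle_translate <- function(s) {
  n <- nchar(s) - nchar(s) %% 3
  if (n < 3) return("")
  paste(Biostrings::GENETIC_CODE[substring(s, seq(1, n, 3), seq(3, n, 3))],
        collapse = "")
}

# rebuilds the whole mutant CDS base-by-base from the genome, translates the
# full reference and mutant proteins and classifies from the protein diff
oracle_effect <- function(site, gm, genome, gene_id) {
  seg <- gm$cds[gm$cds$gene_id == gene_id, ]
  seg <- seg[order(seg$start), ]
  chrom_seq <- as.character(genome[[site$chrom]])
  pos_vec <- unlist(lapply(seq_len(nrow(seg)), function(k) seg$start[k]:seg$end[k]))
  base_vec <- strsplit(chrom_seq, "")[[1]][pos_vec]
  ref_cds <- paste(base_vec, collapse = "")
  mut_base <- base_vec
  mut_pos <- pos_vec
  if (site$vtype == "SNP") {
    mut_base[mut_pos == site$pos] <- site$alt
  } else if (site$vtype == "deletion") {
    del <- (site$pos + 1):(site$pos + nchar(site$ref) - 1)
    keep <- !(mut_pos %in% del)
    mut_base <- mut_base[keep]; mut_pos <- mut_pos[keep]
  } else {
    ins <- strsplit(substr(site$alt, 2, nchar(site$alt)), "")[[1]]
    at <- which(mut_pos == site$pos)
    stopifnot(length(at) == 1)
    mut_base <- append(mut_base, ins, after = at)
  }
  mut_cds <- paste(mut_base, collapse = "")
  strand <- seg$strand[1]
  rc <- function(s) as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  if (strand == "-") { ref_cds <- rc(ref_cds); mut_cds <- rc(mut_cds) }
  pr <- oracle_translate(ref_cds); pm <- oracle_translate(mut_cds)
  nstop <- function(p) lengths(regmatches(p, gregexpr("*", p, fixed = TRUE)))
  dlen <- nchar(mut_cds) - nchar(ref_cds)
  if (site$vtype != "SNP" && dlen %% 3 != 0) {
    return(if (dlen > 0) "frameshift insertion" else "frameshift deletion")
  }
  ds <- nstop(pm) - nstop(pr)
  if (site$vtype == "SNP") {
    if (pm == pr) return("synonymous")
    if (ds > 0) return("stopgain")
    if (ds < 0) return("stoploss")
    return("nonsynonymous")
  }
  if (ds > 0) return("stopgain")
  if (ds < 0) return("stoploss")
  if (site$vtype == "insertion") "non-frameshift insertion" else "non-frameshift deletion"
}

# random exonic variants (SNPs and 1-6 bp indels fully inside CDS segments)
random_exonic_variants <- function(gm, genome, n) {
  cds <- gm$cds
  samp1 <- function(v) v[sample.int(length(v), 1)]  # safe for length-1 vectors
  out <- vector("list", n)
  for (i in seq_len(n)) {
    k <- sample.int(nrow(cds), 1)
    seg <- cds[k, ]
    type <- sample(c("SNP", "insertion", "deletion"), 1,
                   prob = c(0.5, 0.25, 0.25))
    if (seg$end - seg$start < 2) type <- "SNP"
    chrom_seq <- genome[[seg$chrom]]
    if (type == "SNP") {
      pos <- samp1(seg$start:seg$end)
      ref <- as.character(Biostrings::subseq(chrom_seq, pos, pos))
      alt <- samp1(setdiff(c("A", "C", "G", "T"), ref))
    } else if (type == "insertion") {
      pos <- samp1(seg$start:(seg$end - 1))  # pos and pos+1 in the CDS
      ref <- as.character(Biostrings::subseq(chrom_seq, pos, pos))
      len <- sample.int(6, 1)
      alt <- paste0(ref, paste(sample(c("A", "C", "G", "T"), len,
                                      replace = TRUE), collapse = ""))
    } else {
      len <- sample.int(min(6, seg$end - seg$start), 1)
      pos <- samp1(seg$start:(seg$end - len))
      ref <- as.character(Biostrings::subseq(chrom_seq, pos, pos + len))
      alt <- substr(ref, 1, 1)
    }
    out[[i]] <- data.frame(chrom = seg$chrom, pos = pos, ref = ref, alt = alt,
                           vtype = type, gene_id = seg$gene_id,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

# ---- brute-force moment oracle ---------------------------------------------

brute_force_summary <- function(x, p1, p2) {
  n <- length(x)
  mu <- sum(x) / n
  m2 <- sum((x - mu)^2) / n
  m3 <- sum((x - mu)^3) / n
  m4 <- sum((x - mu)^4) / n
  s <- sqrt(sum((x - mu)^2) / (n - 1))
  list(v_mp = (p1 + p2) / 2, f1_mean = mu, f1_sd = s,
       cv_pct = 100 * s / mu,
       hh_pct = 100 * sum(x > max(p1, p2)) / n,
       rhm_pct = 100 * (mu - (p1 + p2) / 2) / ((p1 + p2) / 2),
       skewness = m3 / m2^1.5, kurtosis = m4 / m2^2 - 3)
}

# ---- small simulated fixtures ----------------------------------------------

small_sim_config <- function(seed = 42, ...) {
  sim_config(chromosomes = c(chr1 = 2e6, chr2 = 1e6), marker_density = 60,
             qtl = list(chrom = "chr1", pos = 1e6, effect = 1),
             n_progeny = 120, pool_size = 20, seed = seed, ...)
}

# minimal hand-built truth object for unit-testing pool selection / reads
fake_truth <- function(phenotype, genotypes, markers = NULL, seg_model = "1:1") {
  n <- length(phenotype)
  ids <- sprintf("L%03d", seq_len(n))
  names(phenotype) <- ids
  rownames(genotypes) <- ids
  if (is.null(markers)) {
    m <- ncol(genotypes)
    markers <- data.frame(marker_id = sprintf("M%06d", 1:m), chrom = "chr1",
                          pos = seq(1000, by = 1000, length.out = m),
                          ref = "A", alt = "G", vtype = "SNP",
                          stringsAsFactors = FALSE)
  }
  cfg <- sim_config(n_progeny = max(n, 4), chromosomes = c(chr1 = 1e8),
                    pool_size = max(1, floor(n / 2)), seg_model = seg_model,
                    qtl = NULL)
  structure(list(config = cfg, markers = markers, genotypes = genotypes,
                 phenotype = phenotype, line_ids = ids, qtl = NULL),
            class = "sim_truth")
}
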
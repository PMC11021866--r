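# Variant location and coding-consequence annotation against gene models.
# Coordinates are 1-based inclusive (VCF/GFF3 native). A variant's affected
# range is: SNP [pos, pos]; insertion [pos, pos+1] (anchor base plus the
# base after the insertion point); deletion [pos+1, pos+len-1] (the VCF
# anchor base itself is unchanged).

affected_ranges <- function(sites) {
  start <- ifelse(sites$vtype == "deletion", sites$pos + 1L, sites$pos)
  end <- ifelse(sites$vtype == "SNP", sites$pos,
                ifelse(sites$vtype == "insertion", sites$pos + 1L,
                       sites$pos + nchar(sites$ref) - 1L))
  GenomicRanges::GRanges(sites$chrom, IRanges::IRanges(start, end))
}

gene_feature_ranges <- function(gm, flank = 1000, splice_window = 2) {
  gr <- function(df) {
    GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end),
                           gene_id = df$gene_id)
  }
  empty_gr <- function() {
    g <- GenomicRanges::GRanges()
    S4Vectors::mcols(g)$gene_id <- character(0)
    g
  }
  genes_gr <- gr(gm$genes)
  cds_gr <- gr(gm$cds)
  # introns: gene span minus CDS, per gene
  cds_by_gene <- S4Vectors::split(IRanges::ranges(cds_gr), gm$cds$gene_id)
  intr <- list()
  for (i in seq_len(nrow(gm$genes))) {
    g <- gm$genes$gene_id[i]
    segs <- if (g %in% names(cds_by_gene)) cds_by_gene[[g]] else IRanges::IRanges()
    gaps <- IRanges::setdiff(IRanges::IRanges(gm$genes$start[i], gm$genes$end[i]),
                             segs)
    if (length(gaps)) {
      intr[[length(intr) + 1L]] <- GenomicRanges::GRanges(
        gm$genes$chrom[i], gaps, gene_id = g)
    }
  }
  intron_gr <- if (length(intr)) suppressWarnings(do.call(c, intr)) else empty_gr()
  # splice regions: first/last splice_window bases inside each intron
  sw <- splice_window
  if (length(intron_gr)) {
    s <- GenomicRanges::start(intron_gr); e <- GenomicRanges::end(intron_gr)
    donor <- GenomicRanges::GRanges(GenomicRanges::seqnames(intron_gr),
                                    IRanges::IRanges(s, pmin(s + sw - 1L, e)),
                                    gene_id = intron_gr$gene_id)
    accept <- GenomicRanges::GRanges(GenomicRanges::seqnames(intron_gr),
                                     IRanges::IRanges(pmax(e - sw + 1L, s), e),
                                     gene_id = intron_gr$gene_id)
    splice_gr <- c(donor, accept)
  } else splice_gr <- empty_gr()
  plus <- gm$genes$strand != "-"
  up_start <- ifelse(plus, pmax(gm$genes$start - flank, 1L), gm$genes$end + 1L)
  up_end <- ifelse(plus, gm$genes$start - 1L, gm$genes$end + flank)
  dn_start <- ifelse(plus, gm$genes$end + 1L, pmax(gm$genes$start - flank, 1L))
  dn_end <- ifelse(plus, gm$genes$end + flank, gm$genes$start - 1L)
  ok_up <- up_end >= up_start; ok_dn <- dn_end >= dn_start
  up_gr <- GenomicRanges::GRanges(gm$genes$chrom[ok_up],
                                  IRanges::IRanges(up_start[ok_up], up_end[ok_up]),
                                  gene_id = gm$genes$gene_id[ok_up])
  dn_gr <- GenomicRanges::GRanges(gm$genes$chrom[ok_dn],
                                  IRanges::IRanges(dn_start[ok_dn], dn_end[ok_dn]),
                                  gene_id = gm$genes$gene_id[ok_dn])
  list(genes = genes_gr, cds = cds_gr, intron = intron_gr, splice = splice_gr,
       up = up_gr, down = dn_gr)
}

hit_genes <- function(query, subject) {
  out <- vector("list", length(query))
  ov <- suppressWarnings(GenomicRanges::findOverlaps(query, subject))
  if (length(ov)) {
    sp <- split(subject$gene_id[S4Vectors::subjectHits(ov)],
                S4Vectors::queryHits(ov))
    out[as.integer(names(sp))] <- lapply(sp, function(g) sort(unique(g)))
  }
  out
}

#' Classify variant genomic location
#'
#' Assigns each variant exactly one location with precedence
#' exonic > splicing > intronic > upstream/downstream > intergenic.
#' "Exonic" means the affected range intersects a CDS segment; "splicing"
#' means it lies within `splice_window` bases of an intron boundary (inside
#' the intron); "upstream"/"downstream" are strand-aware windows of `flank`
#' bp beyond the gene span, and a variant simultaneously upstream of one
#' gene and downstream of another is labelled "upstream/downstream".
#'
#' @param sites variant-site data.frame (`chrom, pos, ref, alt, vtype`).
#' @param genes a [gene_models()] object.
#' @param flank upstream/downstream window (bp).
#' @param splice_window splice-region width inside the intron (bp).
#' @param chrom_lengths optional named vector; variants beyond a chromosome
#'   end raise an error.
#' @return data.frame with `location` and comma-collapsed `gene_ids`.
#' @export
classify_location <- function(sites, genes, flank = 1000, splice_window = 2,
                              chrom_lengths = NULL) {
  if (!is.null(chrom_lengths)) {
    bad <- sites$pos > chrom_lengths[sites$chrom] | is.na(chrom_lengths[sites$chrom])
    if (any(bad)) {
      stop("variant position beyond chromosome length at ",
           paste(utils::head(paste0(sites$chrom[bad], ":", sites$pos[bad]), 5),
                 collapse = ", "), call. = FALSE)
    }
  }
  feats <- gene_feature_ranges(genes, flank = flank, splice_window = splice_window)
  q <- affected_ranges(sites)
  h_cds <- hit_genes(q, feats$cds)
  h_spl <- hit_genes(q, feats$splice)
  h_int <- hit_genes(q, feats$intron)
  h_up <- hit_genes(q, feats$up)
  h_dn <- hit_genes(q, feats$down)
  n <- nrow(sites)
  location <- character(n); gene_ids <- character(n)
  for (i in seq_len(n)) {
    if (!is.null(h_cds[[i]])) {
      location[i] <- "exonic"; gene_ids[i] <- paste(h_cds[[i]], collapse = ",")
    } else if (!is.null(h_spl[[i]])) {
      location[i] <- "splicing"; gene_ids[i] <- paste(h_spl[[i]], collapse = ",")
    } else if (!is.null(h_int[[i]])) {
      location[i] <- "intronic"; gene_ids[i] <- paste(h_int[[i]], collapse = ",")
    } else if (!is.null(h_up[[i]]) && !is.null(h_dn[[i]])) {
      location[i] <- "upstream/downstream"
      gene_ids[i] <- paste(sort(unique(c(h_up[[i]], h_dn[[i]]))), collapse = ",")
    } else if (!is.null(h_up[[i]])) {
      location[i] <- "upstream"; gene_ids[i] <- paste(h_up[[i]], collapse = ",")
    } else if (!is.null(h_dn[[i]])) {
      location[i] <- "downstream"; gene_ids[i] <- paste(h_dn[[i]], collapse = ",")
    } else {
      location[i] <- "intergenic"; gene_ids[i] <- ""
    }
  }
  data.frame(location = location, gene_ids = gene_ids, stringsAsFactors = FALSE)
}

# per-gene context for consequence calls: CDS sequence in transcript
# orientation plus the genomic-ascending segment table
gene_cds_context <- function(gm, genome, gene_id) {
  seg <- gm$cds[gm$cds$gene_id == gene_id, ]
  seg <- seg[order(seg$start), ]
  chrom <- seg$chrom[1]
  pieces <- vapply(seq_len(nrow(seg)), function(k) {
    as.character(Biostrings::subseq(genome[[chrom]], seg$start[k], seg$end[k]))
  }, "")
  genomic_seq <- paste(pieces, collapse = "")
  strand <- seg$strand[1]
  tx <- if (strand == "-") {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(genomic_seq)))
  } else genomic_seq
  w <- seg$end - seg$start + 1
  list(strand = strand, seg = seg, cum_before = cumsum(c(0, w))[seq_along(w)],
       L = sum(w), cds = tx)
}

# 1-based offset of genomic position p within the genomic-ascending CDS
# concatenation, or NA when p is not in the CDS
genomic_cds_offset <- function(ctx, p) {
  k <- which(ctx$seg$start <= p & p <= ctx$seg$end)
  if (!length(k)) return(NA_integer_)
  ctx$cum_before[k[1]] + (p - ctx$seg$start[k[1]] + 1L)
}

tx_coord <- function(ctx, p) {
  off <- genomic_cds_offset(ctx, p)
  if (is.na(off)) return(NA_integer_)
  if (ctx$strand == "-") ctx$L - off + 1L else off
}

translate_str <- function(s) {
  n <- nchar(s) - nchar(s) %% 3
  if (n < 3) return("")
  cod <- substring(s, seq(1, n, 3), seq(3, n, 3))
  paste(Biostrings::GENETIC_CODE[cod], collapse = "")
}

count_stops <- function(pep) lengths(regmatches(pep, gregexpr("*", pep, fixed = TRUE)))

revcomp_str <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

effect_one <- function(ctx, site) {
  cds <- ctx$cds; L <- ctx$L
  if (site$vtype == "SNP") {
    c0 <- tx_coord(ctx, site$pos)
    if (is.na(c0)) return(NA_character_)
    alt_tx <- if (ctx$strand == "-") revcomp_str(site$alt) else site$alt
    a <- (c0 - 1) %/% 3 * 3 + 1
    codon <- substr(cds, a, min(a + 2, L))
    if (nchar(codon) < 3) return("nonsynonymous")  # incomplete terminal codon
    mut <- codon
    substr(mut, c0 - a + 1, c0 - a + 1) <- alt_tx
    aa_r <- Biostrings::GENETIC_CODE[codon]
    aa_a <- Biostrings::GENETIC_CODE[mut]
    if (aa_r == aa_a) return("synonymous")
    if (aa_a == "*") return("stopgain")
    if (aa_r == "*") return("stoploss")
    return("nonsynonymous")
  }
  if (site$vtype == "insertion") {
    ins <- substr(site$alt, 2, nchar(site$alt))
    in_pos <- !is.na(genomic_cds_offset(ctx, site$pos))
    in_next <- !is.na(genomic_cds_offset(ctx, site$pos + 1L))
    if (!in_pos && !in_next) return(NA_character_)
    c_after <- if (ctx$strand == "-") {
      if (in_next) tx_coord(ctx, site$pos + 1L) else tx_coord(ctx, site$pos) - 1L
    } else {
      if (in_pos) tx_coord(ctx, site$pos) else tx_coord(ctx, site$pos + 1L) - 1L
    }
    len <- nchar(ins)
    if (len %% 3 != 0) return("frameshift insertion")
    ins_tx <- if (ctx$strand == "-") revcomp_str(ins) else ins
    a <- (max(c_after, 1L) - 1) %/% 3 * 3 + 1
    b <- min((min(c_after + 1L, L) - 1) %/% 3 * 3 + 3, L)
    ref_local <- substr(cds, a, b)
    alt_local <- paste0(substr(cds, a, c_after), ins_tx,
                        substr(cds, c_after + 1L, b))
    d <- count_stops(translate_str(alt_local)) - count_stops(translate_str(ref_local))
    if (d > 0) return("stopgain")
    if (d < 0) return("stoploss")
    return("non-frameshift insertion")
  }
  # deletion: genomic range pos+1 .. pos+len(ref)-1
  del <- seq.int(site$pos + 1L, site$pos + nchar(site$ref) - 1L)
  txc <- vapply(del, function(p) as.integer(tx_coord(ctx, p)), integer(1))
  txc <- txc[!is.na(txc)]
  if (!length(txc)) return(NA_character_)
  if (length(txc) %% 3 != 0) return("frameshift deletion")
  c1 <- min(txc); c2 <- max(txc)
  a <- (c1 - 1) %/% 3 * 3 + 1
  b <- min((c2 - 1) %/% 3 * 3 + 3, L)
  ref_local <- substr(cds, a, b)
  alt_local <- paste0(substr(cds, a, c1 - 1L), substr(cds, c2 + 1L, b))
  d <- count_stops(translate_str(alt_local)) - count_stops(translate_str(ref_local))
  if (d > 0) return("stopgain")
  if (d < 0) return("stoploss")
  "non-frameshift deletion"
}

effect_severity <- c("stopgain" = 1, "stoploss" = 2,
                     "frameshift insertion" = 3, "frameshift deletion" = 3,
                     "nonsynonymous" = 4, "splicing" = 4.5,
                     "non-frameshift insertion" = 5,
                     "non-frameshift deletion" = 5, "synonymous" = 6,
                     "none" = 99)

#' Classify the coding consequence of exonic variants
#'
#' SNPs are classified by translating the reference and alternate codon
#' (reverse-complemented on minus-strand genes) with the standard nuclear
#' code: synonymous, nonsynonymous, stopgain or stoploss. InDels whose
#' in-CDS length is not a multiple of 3 are frameshift insertions/
#' deletions; in-frame InDels are non-frameshift unless the local codon
#' window gains or loses a stop codon (stopgain/stoploss take precedence).
#' With several overlapping genes the most severe consequence wins.
#'
#' @param sites variant-site data.frame; every row must be exonic.
#' @param genes a [gene_models()] object.
#' @param genome named [Biostrings::DNAStringSet].
#' @param gene_ids optional character vector (comma-collapsed) of the CDS
#'   genes per site, as returned by [classify_location()]; computed when
#'   missing.
#' @return character vector of consequences.
#' @export
classify_exonic_effect <- function(sites, genes, genome, gene_ids = NULL) {
  if (is.null(gene_ids)) {
    loc <- classify_location(sites, genes)
    if (any(loc$location != "exonic")) {
      stop("classify_exonic_effect() requires exonic variants", call. = FALSE)
    }
    gene_ids <- loc$gene_ids
  }
  # reference-allele sanity check against the genome
  for (i in seq_len(nrow(sites))) {
    obs <- as.character(Biostrings::subseq(
      genome[[sites$chrom[i]]], sites$pos[i],
      sites$pos[i] + nchar(sites$ref[i]) - 1L))
    if (obs != sites$ref[i]) {
      stop(sprintf("reference allele mismatch at %s:%d (VCF %s, genome %s)",
                   sites$chrom[i], sites$pos[i], sites$ref[i], obs),
           call. = FALSE)
    }
  }
  ctx_cache <- new.env(parent = emptyenv())
  get_ctx <- function(g) {
    if (is.null(ctx_cache[[g]])) ctx_cache[[g]] <- gene_cds_context(genes, genome, g)
    ctx_cache[[g]]
  }
  vapply(seq_len(nrow(sites)), function(i) {
    gs <- strsplit(gene_ids[i], ",", fixed = TRUE)[[1]]
    effs <- vapply(gs, function(g) {
      e <- effect_one(get_ctx(g), sites[i, ])
      if (is.na(e)) "none" else e
    }, "")
    effs[which.min(effect_severity[effs])]
  }, "")
}

#' Annotate variants: location plus coding consequence
#'
#' Runs [classify_location()] on all sites and [classify_exonic_effect()]
#' on the exonic subset (which requires `genome`). Non-exonic variants get
#' `exonic_effect = "none"`.
#'
#' @inheritParams classify_location
#' @param genome named [Biostrings::DNAStringSet], required when any
#'   variant is exonic.
#' @return the input data.frame with `location`, `gene_ids` and
#'   `exonic_effect` columns appended.
#' @export
annotate_variants <- function(sites, genes, genome = NULL, flank = 1000,
                              splice_window = 2, chrom_lengths = NULL) {
  loc <- classify_location(sites, genes, flank = flank,
                           splice_window = splice_window,
                           chrom_lengths = chrom_lengths)
  out <- cbind(sites, loc)
  out$exonic_effect <- rep("none", nrow(out))
  ex <- which(loc$location == "exonic")
  if (length(ex)) {
    if (is.null(genome)) {
      stop("`genome` is required to classify exonic consequences", call. = FALSE)
    }
    out$exonic_effect[ex] <- classify_exonic_effect(
      sites[ex, , drop = FALSE], genes, genome, gene_ids = loc$gene_ids[ex])
  }
  class(out) <- c("annotated_variants", "data.frame")
  out
}

#' Transition/transversion ratio
#'
#' Transitions are A<->G and C<->T; everything else is a transversion.
#' Returns `Inf` when there are transitions but no transversions and `NA`
#' when there are neither.
#'
#' @param ts,tv transition and transversion counts.
#' @return the ratio (unrounded).
#' @export
#' @examples
#' tstv_ratio(2260594, 1292240) # 1.749 at 3 decimals
tstv_ratio <- function(ts, tv) {
  if (tv == 0) return(if (ts > 0) Inf else NA_real_)
  ts / tv
}

is_transition <- function(ref, alt) {
  (ref == "A" & alt == "G") | (ref == "G" & alt == "A") |
    (ref == "C" & alt == "T") | (ref == "T" & alt == "C")
}

#' Annotation census: category counts and Ts/Tv accounting
#'
#' Tabulates SNPs and InDels by location (exonic split by consequence),
#' counts transitions/transversions and insertions/deletions, and reports
#' the Ts/Tv ratio to 3 decimals.
#'
#' @param annotated output of [annotate_variants()].
#' @return list with `snp` and `indel` count tables, `ts`, `tv`,
#'   `tstv` (3 dp), `n_insertion`, `n_deletion`, `total_snp`, `total_indel`.
#' @export
annotation_census <- function(annotated) {
  snp <- annotated[annotated$vtype == "SNP", , drop = FALSE]
  ind <- annotated[annotated$vtype != "SNP", , drop = FALSE]
  tab <- function(df, exon_levels) {
    cat_of <- ifelse(df$location == "exonic", df$exonic_effect, df$location)
    levels <- c("upstream", exon_levels, "intronic", "splicing", "downstream",
                "upstream/downstream", "intergenic")
    counts <- table(factor(cat_of, levels = levels))
    data.frame(category = levels, count = as.integer(counts),
               stringsAsFactors = FALSE)
  }
  snp_tab <- tab(snp, c("stopgain", "stoploss", "synonymous", "nonsynonymous"))
  ind_tab <- tab(ind, c("stopgain", "stoploss", "frameshift deletion",
                        "frameshift insertion", "non-frameshift deletion",
                        "non-frameshift insertion"))
  ts <- sum(is_transition(snp$ref, snp$alt))
  tv <- nrow(snp) - ts
  list(snp = snp_tab, indel = ind_tab,
       ts = ts, tv = tv,
       tstv = round(tstv_ratio(ts, tv), 3),
       n_insertion = sum(ind$vtype == "insertion"),
       n_deletion = sum(ind$vtype == "deletion"),
       total_snp = nrow(snp), total_indel = nrow(ind))
}
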
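# Candidate-gene screening from annotated polymorphic loci.

candidate_tier <- function(location, exonic_effect) {
  eff <- ifelse(location == "exonic", exonic_effect, location)
  ifelse(eff %in% c("stopgain", "stoploss", "frameshift insertion",
                    "frameshift deletion"), 1L,
         ifelse(eff %in% c("nonsynonymous", "splicing"), 2L,
                ifelse(eff %in% c("upstream", "downstream",
                                  "upstream/downstream"), 3L, NA_integer_)))
}

#' Screen candidate genes from annotated variants
#'
#' Applies the consequence preference rule in three tiers: tier 1 variants
#' disrupt the product outright (stopgain, stoploss, frameshift); tier 2
#' change it (nonsynonymous, splice-region); tier 3 (on by default) are
#' regulatory-region candidates (upstream/downstream). Records are expanded
#' to one row per (gene, variant), deduplicated, and sorted by tier, then
#' chromosome and position.
#'
#' @param annotated output of [annotate_variants()] (typically restricted
#'   to the filtered polymorphic loci).
#' @param intervals optional `candidate_intervals`; sets the `in_interval`
#'   flag and, in `"interval-restricted"` mode, drops loci outside them.
#' @param mode `"genome-wide"` (default) or `"interval-restricted"`.
#' @param include_updown keep tier-3 upstream/downstream candidates.
#' @param descriptions optional data.frame `gene_id, description` sidecar.
#' @return a `candidate_genes` data.frame: `gene_id, variant_class,
#'   consequence, chrom, pos, ref, alt, tier, in_interval, description`.
#' @export
screen_candidates <- function(annotated, intervals = NULL,
                              mode = c("genome-wide", "interval-restricted"),
                              include_updown = TRUE, descriptions = NULL) {
  mode <- match.arg(mode)
  tier <- candidate_tier(annotated$location, annotated$exonic_effect)
  keep <- !is.na(tier) & (include_updown | tier < 3L)
  df <- annotated[keep, , drop = FALSE]
  tier <- tier[keep]
  if (!nrow(df)) return(empty_candidates())
  # one row per (gene, variant)
  gl <- strsplit(df$gene_ids, ",", fixed = TRUE)
  rep_ix <- rep(seq_len(nrow(df)), lengths(gl))
  out <- data.frame(
    gene_id = unlist(gl),
    variant_class = ifelse(df$vtype[rep_ix] == "SNP", "SNP", "InDel"),
    consequence = ifelse(df$location[rep_ix] == "exonic",
                         df$exonic_effect[rep_ix], df$location[rep_ix]),
    chrom = df$chrom[rep_ix], pos = df$pos[rep_ix],
    ref = df$ref[rep_ix], alt = df$alt[rep_ix],
    tier = tier[rep_ix], stringsAsFactors = FALSE)
  out$in_interval <- FALSE
  if (!is.null(intervals) && nrow(intervals)) {
    igr <- GenomicRanges::GRanges(intervals$chrom,
                                  IRanges::IRanges(intervals$start + 1,
                                                   intervals$end))
    vgr <- GenomicRanges::GRanges(out$chrom, IRanges::IRanges(out$pos, out$pos))
    out$in_interval <- suppressWarnings(IRanges::overlapsAny(vgr, igr))
  }
  if (mode == "interval-restricted") {
    if (is.null(intervals)) {
      stop("interval-restricted mode requires `intervals`", call. = FALSE)
    }
    out <- out[out$in_interval, , drop = FALSE]
  }
  out <- out[!duplicated(out[c("gene_id", "chrom", "pos", "ref", "alt")]), ,
             drop = FALSE]
  out <- out[order(out$tier, out$chrom, out$pos, out$gene_id), , drop = FALSE]
  out$description <- if (!is.null(descriptions)) {
    descriptions$description[match(out$gene_id, descriptions$gene_id)]
  } else NA_character_
  rownames(out) <- NULL
  class(out) <- c("candidate_genes", "data.frame")
  out
}

empty_candidates <- function() {
  out <- data.frame(gene_id = character(), variant_class = character(),
                    consequence = character(), chrom = character(),
                    pos = integer(), ref = character(), alt = character(),
                    tier = integer(), in_interval = logical(),
                    description = character(), stringsAsFactors = FALSE)
  class(out) <- c("candidate_genes", "data.frame")
  out
}

#' Summarize a candidate-gene screen
#'
#' @param records output of [screen_candidates()].
#' @return list with per-class candidate locus counts, the distinct gene
#'   count, per-chromosome gene distribution and per-consequence counts.
#' @export
summarize_screen <- function(records) {
  loci <- unique(records[c("variant_class", "chrom", "pos", "ref", "alt")])
  by_chrom <- if (nrow(records)) {
    tab <- table(records$chrom[!duplicated(records$gene_id)])
    data.frame(chrom = names(tab), n_genes = as.integer(tab),
               stringsAsFactors = FALSE)
  } else data.frame(chrom = character(), n_genes = integer())
  list(
    n_loci_snp = sum(loci$variant_class == "SNP"),
    n_loci_indel = sum(loci$variant_class == "InDel"),
    n_genes = length(unique(records$gene_id)),
    n_genes_annotated = length(unique(
      records$gene_id[!is.na(records$description)])),
    genes_by_chrom = by_chrom,
    by_consequence = if (nrow(records)) {
      as.data.frame(table(consequence = records$consequence),
                    stringsAsFactors = FALSE)
    } else data.frame(consequence = character(), Freq = integer()))
}
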
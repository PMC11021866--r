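# End-to-end pipeline: phenotype stats -> annotation -> index association
# (SNP, InDel, All) -> candidate genes, with deterministic table outputs
# and a JSON manifest.

#' Pipeline configuration
#'
#' Bundles the input paths, the VCF sample-role map and all stage
#' parameters. The four roles must map to distinct VCF sample names.
#'
#' @param vcf multi-sample VCF with per-sample AD fields.
#' @param gff3 gene annotation (GFF3).
#' @param phenotypes per-line phenotype TSV (see [read_phenotypes()]).
#' @param out_dir output directory.
#' @param fasta optional genome FASTA (required for coding consequences).
#' @param roles named character vector mapping `parent_f, parent_m,
#'   pool_large, pool_small` to VCF sample names.
#' @param window,step sliding-window width and stride (bp).
#' @param min_index,min_depth site filter thresholds.
#' @param pool_size lines per pool (phenotype screen and null CI).
#' @param seg_model segregation model for the null CI simulation.
#' @param n_sims null simulations per depth key.
#' @param level confidence level for significance calling.
#' @param flank,splice_window annotation distances (bp).
#' @param min_abs_delta optional absolute delta floor for calling.
#' @param aux_slack auxiliary-trait slack quantile for the extreme screen
#'   (`NULL` disables the auxiliary filter).
#' @param seed RNG seed for the null CI simulation.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(vcf, gff3, phenotypes, out_dir, fasta = NULL,
                            roles = c(parent_f = "parent_female",
                                      parent_m = "parent_male",
                                      pool_large = "pool_large",
                                      pool_small = "pool_small"),
                            window = 1e6, step = 1e3, min_index = 0.3,
                            min_depth = 7, pool_size = 30,
                            seg_model = "1:1", n_sims = 10000, level = 0.95,
                            flank = 1000, splice_window = 2,
                            min_abs_delta = 0, aux_slack = NULL, seed = 1L) {
  need <- c("parent_f", "parent_m", "pool_large", "pool_small")
  if (!all(need %in% names(roles)) || anyDuplicated(roles)) {
    stop("`roles` must assign the four roles to distinct sample names",
         call. = FALSE)
  }
  stopifnot(window >= step, step > 0, level > 0, level < 1)
  structure(list(vcf = vcf, gff3 = gff3, phenotypes = phenotypes,
                 out_dir = out_dir, fasta = fasta, roles = roles[need],
                 window = window, step = step, min_index = min_index,
                 min_depth = min_depth, pool_size = pool_size,
                 seg_model = seg_model, n_sims = n_sims, level = level,
                 flank = flank, splice_window = splice_window,
                 min_abs_delta = min_abs_delta, aux_slack = aux_slack,
                 seed = seed), class = "pipeline_config")
}

vcf_contig_lengths <- function(path) {
  hdr <- grep("^##contig=", readLines(path, n = 5000), value = TRUE)
  id <- sub('.*[<,]ID=([^,>]+).*', "\\1", hdr)
  len <- suppressWarnings(as.numeric(sub(".*length=([0-9]+).*", "\\1", hdr)))
  stats::setNames(len, id)[!is.na(len)]
}

#' Run the full QTL-seq pipeline
#'
#' Executes phenotype statistics, variant annotation, the SNP-/InDel-/
#' All-index association scans and candidate-gene screening, writing every
#' table (TSV/BED/JSON) under `config$out_dir`. Reruns with an identical
#' configuration and seed produce byte-identical outputs.
#'
#' @param config a [pipeline_config()].
#' @return the run manifest (named list), invisibly; also written as
#'   `manifest.json`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)
  out <- function(f) file.path(config$out_dir, f)

  ## phenotype stage
  pheno <- read_phenotypes(config$phenotypes)
  has_parents <- all(c("parent_f", "parent_m") %in% pheno$role)
  if (has_parents) {
    ts <- trait_summary_table(pheno)
    write_tsv_plain(ts, out("trait_summary.tsv"))
  }
  scr <- screen_extremes(pheno, config$pool_size, aux_slack = config$aux_slack)
  write_tsv_plain(data.frame(pool = rep(c("large", "small"),
                                        each = config$pool_size),
                             line_id = c(scr$large, scr$small)),
                  out("pool_members.tsv"))
  write_tsv_plain(scr$summary, out("pool_summary.tsv"))

  ## inputs for the genomic stages
  chrom_lengths <- vcf_contig_lengths(config$vcf)
  if (!length(chrom_lengths)) {
    stop("VCF header carries no ##contig lengths", call. = FALSE)
  }
  sites <- read_variant_sites(config$vcf, roles = config$roles)
  genes <- read_gene_models(config$gff3)
  missing_chr <- setdiff(unique(genes$genes$chrom), names(chrom_lengths))
  if (length(missing_chr)) {
    stop("chromosome names in the GFF3 absent from the VCF contigs: ",
         paste(missing_chr, collapse = ", "), call. = FALSE)
  }
  genome <- if (!is.null(config$fasta)) {
    g <- Biostrings::readDNAStringSet(config$fasta)
    names(g) <- sub("\\s.*", "", names(g))
    g
  }
  if (!nrow(sites)) warning("VCF contains zero variants; writing empty outputs")

  ## annotation stage
  ann <- annotate_variants(sites, genes, genome = genome,
                           flank = config$flank,
                           splice_window = config$splice_window,
                           chrom_lengths = chrom_lengths)
  census <- annotation_census(ann)
  write_tsv_plain(census$snp, out("census_snp.tsv"))
  write_tsv_plain(census$indel, out("census_indel.tsv"))

  ## index association stage
  roles <- config$roles
  idx_of <- function(sub) {
    rec <- compute_indices(sub, large = roles[["pool_large"]],
                           small = roles[["pool_small"]])
    filter_records(rec, config$min_index, config$min_depth)
  }
  snp_rec <- idx_of(sites[sites$vtype == "SNP", , drop = FALSE])
  ind_rec <- idx_of(sites[sites$vtype != "SNP", , drop = FALSE])
  write_tsv_plain(snp_rec, out("index_snp.tsv"))
  write_tsv_plain(ind_rec, out("index_indel.tsv"))

  scan0 <- function(rec) sliding_window_scan(rec, chrom_lengths,
                                             config$window, config$step)
  pre <- scan0(rbind(snp_rec, ind_rec))
  keys <- unique(c(round((snp_rec$depth_large + snp_rec$depth_small) / 2),
                   round((ind_rec$depth_large + ind_rec$depth_small) / 2),
                   round(pre$mean_depth[!is.na(pre$mean_depth)])))
  ci <- if (length(keys)) {
    simulate_null_ci(keys, pool_size = config$pool_size,
                     seg_model = config$seg_model, n_sims = config$n_sims,
                     min_index = config$min_index,
                     min_depth = config$min_depth)
  }
  scans <- list(
    snp = sliding_window_scan(snp_rec, chrom_lengths, config$window,
                              config$step, ci = ci, level = config$level,
                              min_abs_delta = config$min_abs_delta),
    indel = sliding_window_scan(ind_rec, chrom_lengths, config$window,
                                config$step, ci = ci, level = config$level,
                                min_abs_delta = config$min_abs_delta),
    all = all_index_scan(snp_rec, ind_rec, chrom_lengths, config$window,
                         config$step, ci = ci, level = config$level,
                         min_abs_delta = config$min_abs_delta))
  classes <- c(snp = "SNP", indel = "InDel", all = "All")
  intervals <- list()
  for (nm in names(scans)) {
    write_tsv_plain(scans[[nm]], out(sprintf("scan_%s.tsv", nm)))
    iv <- call_intervals(scans[[nm]], genes = genes,
                         marker_class = classes[[nm]])
    intervals[[nm]] <- iv
    write_tsv_plain(iv, out(sprintf("intervals_%s.tsv", nm)))
    write_intervals_bed(iv, out(sprintf("intervals_%s.bed", nm)))
  }

  ## candidate-gene stage: loci that survived filtering, genome-wide screen
  kept <- paste(c(snp_rec$chrom, ind_rec$chrom),
                c(snp_rec$pos, ind_rec$pos),
                c(snp_rec$alt, ind_rec$alt))
  ann_kept <- ann[paste(ann$chrom, ann$pos, ann$alt) %in% kept, , drop = FALSE]
  cands <- screen_candidates(ann_kept, intervals = intervals$all,
                             mode = "genome-wide")
  write_tsv_plain(cands, out("candidates.tsv"))
  csum <- summarize_screen(cands)
  jsonlite::write_json(csum, out("candidate_summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")

  manifest <- list(
    package = "poolscan",
    version = as.character(utils::packageVersion("poolscan")),
    seed = config$seed,
    parameters = config[c("window", "step", "min_index", "min_depth",
                          "pool_size", "seg_model", "n_sims", "level",
                          "flank", "splice_window", "min_abs_delta")],
    roles = as.list(config$roles),
    counts = list(
      n_lines = sum(pheno$role == "F1"),
      n_sites_snp = sum(sites$vtype == "SNP"),
      n_sites_indel = sum(sites$vtype != "SNP"),
      n_filtered_snp = nrow(snp_rec),
      n_filtered_indel = nrow(ind_rec),
      n_windows = nrow(scans$snp),
      n_significant = vapply(scans, function(s)
        sum(s$significant, na.rm = TRUE), integer(1)),
      n_intervals = vapply(intervals, nrow, integer(1)),
      n_candidate_loci = csum$n_loci_snp + csum$n_loci_indel,
      n_candidate_genes = csum$n_genes))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Phred quality score to error probability
#'
#' `10^(-q/10)`: Q20 is an error probability of 0.01, Q30 of 0.001. Used
#' when echoing externally computed Q20/Q30 read-quality summaries.
#'
#' @param q numeric Phred score(s), `>= 0`.
#' @return error probability vector.
#' @export
#' @examples
#' phred_error(c(20, 30)) # 0.01 0.001
phred_error <- function(q) {
  if (any(is.na(q)) || any(q < 0)) stop("q must be >= 0", call. = FALSE)
  10^(-q / 10)
}
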
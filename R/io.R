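# VCF and table I/O. Reading goes through vcfR; the writer is a small
# deterministic text emitter for the simulator's 4-sample output.

#' Write variant sites with per-sample allele depths to VCF 4.2
#'
#' Emits one biallelic record per site with `AD` (ref,alt) and `DP` per
#' sample. Sites are sorted by contig order and position.
#'
#' @param sites a `variant_sites` data.frame (see [simulate_pool_reads()]).
#' @param path output file.
#' @param contig_lengths named vector of contig lengths for the header.
#' @return the path, invisibly.
#' @export
write_variant_vcf <- function(sites, path, contig_lengths) {
  samples <- vcf_samples(sites)
  ord <- order(match(sites$chrom, names(contig_lengths)), sites$pos)
  sites <- sites[ord, , drop = FALSE]
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=poolscan",
    sprintf("##contig=<ID=%s,length=%d>", names(contig_lengths),
            as.integer(contig_lengths)),
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths (ref,alt)\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  geno <- vapply(samples, function(s) {
    r <- sites[[paste0(s, ".ref")]]; a <- sites[[paste0(s, ".alt")]]
    sprintf("%d,%d:%d", r, a, r + a)
  }, character(nrow(sites)))
  if (nrow(sites) == 1L) geno <- matrix(geno, nrow = 1)
  body <- paste(sites$chrom, sites$pos, ".", sites$ref, sites$alt, ".",
                "PASS", ".", "AD:DP",
                apply(geno, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, if (nrow(sites)) body), path)
  invisible(path)
}

vcf_samples <- function(sites) {
  cols <- grep("\\.ref$", names(sites), value = TRUE)
  sub("\\.ref$", "", cols)
}

classify_vtype <- function(ref, alt) {
  ifelse(nchar(ref) == 1 & nchar(alt) == 1, "SNP",
         ifelse(nchar(alt) > nchar(ref), "insertion", "deletion"))
}

#' Read a multi-sample VCF into a variant-site table
#'
#' Parses with \pkg{vcfR}, extracts per-sample `AD` fields, and splits
#' multi-allelic records into one biallelic row per alternate allele
#' (allele k takes AD fields 1 and k+1). Records without an `AD` entry for
#' a sample get zero counts.
#'
#' @param path VCF file (uncompressed or bgzipped).
#' @param roles optional named character vector mapping roles
#'   (`parent_f, parent_m, pool_large, pool_small`) to VCF sample names;
#'   stored as an attribute for downstream stages.
#' @return a `variant_sites` data.frame with columns `chrom, pos, ref, alt,
#'   vtype` and `<sample>.ref` / `<sample>.alt`.
#' @export
read_variant_sites <- function(path, roles = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  n <- nrow(fix)
  samples <- colnames(v@gt)[-1]
  empty <- function() {
    out <- data.frame(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), vtype = character(),
                      stringsAsFactors = FALSE)
    for (s in samples) {
      out[[paste0(s, ".ref")]] <- integer()
      out[[paste0(s, ".alt")]] <- integer()
    }
    out
  }
  if (n == 0) {
    sites <- empty()
  } else {
    ad <- vcfR::extract.gt(v, element = "AD")
    if (is.null(dim(ad))) ad <- matrix(ad, nrow = n,
                                       dimnames = list(NULL, samples))
    alt_list <- strsplit(fix[, "ALT"], ",", fixed = TRUE)
    n_alt <- lengths(alt_list)
    row_ix <- rep(seq_len(n), n_alt)
    alt_ix <- unlist(lapply(n_alt, seq_len))
    ref <- fix[row_ix, "REF"]
    alt <- unlist(alt_list)
    sites <- data.frame(
      chrom = fix[row_ix, "CHROM"],
      pos = as.integer(fix[row_ix, "POS"]),
      ref = ref, alt = alt, vtype = classify_vtype(ref, alt),
      stringsAsFactors = FALSE)
    rownames(sites) <- NULL
    for (s in samples) {
      parts <- strsplit(ad[, s], ",", fixed = TRUE)
      getk <- function(k_vec) {
        vapply(seq_along(row_ix), function(i) {
          p <- parts[[row_ix[i]]]
          k <- k_vec[i]
          if (length(p) < k || is.na(p[k]) || p[k] == ".") 0L
          else as.integer(p[k])
        }, integer(1))
      }
      sites[[paste0(s, ".ref")]] <- getk(rep(1L, length(row_ix)))
      sites[[paste0(s, ".alt")]] <- getk(alt_ix + 1L)
    }
  }
  if (!is.null(roles)) {
    if (!all(roles %in% samples)) {
      stop("roles refer to sample names absent from the VCF: ",
           paste(setdiff(roles, samples), collapse = ", "), call. = FALSE)
    }
    attr(sites, "roles") <- roles
  }
  class(sites) <- c("variant_sites", "data.frame")
  sites
}

#' Read a per-line phenotype table
#'
#' Expects a TSV with `line_id`, optionally a `role` column
#' (`F1`/`parent_f`/`parent_m`), and trait columns. Adds the derived fruit
#' shape index (length / diameter) when both components are present.
#'
#' @param path TSV file.
#' @return data.frame with an added `fruit_shape_index` column.
#' @export
read_phenotypes <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"line_id" %in% names(df)) stop("phenotype table needs a line_id column",
                                      call. = FALSE)
  if (!"role" %in% names(df)) df$role <- "F1"
  if (all(c("fruit_length_mm", "fruit_diameter_mm") %in% names(df))) {
    df$fruit_shape_index <- shape_index(df$fruit_length_mm, df$fruit_diameter_mm)
  }
  df
}

#' Write candidate intervals as BED (0-based half-open)
#'
#' @param intervals interval data.frame from [call_intervals()].
#' @param path output BED file.
#' @return the path, invisibly.
#' @export
write_intervals_bed <- function(intervals, path) {
  if (nrow(intervals)) {
    bed <- data.frame(chrom = intervals$chrom,
                      start = format(intervals$start, scientific = FALSE, trim = TRUE),
                      end = format(intervals$end, scientific = FALSE, trim = TRUE),
                      name = sprintf("interval_%d", seq_len(nrow(intervals))))
    utils::write.table(bed, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  } else {
    file.create(path)
  }
  invisible(path)
}
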
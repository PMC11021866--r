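#' Simulation configuration for a synthetic QTL-seq experiment
#'
#' Describes an outbred F1 (pseudo-testcross) mapping population segregating
#' SNP and InDel markers, one optional fruit-size QTL on a polygenic
#' background, extreme phenotype pools, and pooled short-read sequencing.
#' The defaults mirror a jujube fruit-size QTL-seq design: 284 progeny,
#' pools of 30 lines each, a 1-SD additive QTL at 31 Mb of the largest
#' chromosome, narrow-sense heritability 0.6, and 40x mean pool depth.
#'
#' @param n_progeny number of F1 lines.
#' @param chromosomes named numeric vector of chromosome lengths in bp.
#' @param marker_density segregating markers per Mb.
#' @param snp_fraction fraction of markers that are SNPs; the rest are
#'   short insertions/deletions (1-6 bp).
#' @param qtl list with elements `chrom`, `pos` (bp) and `effect`
#'   (difference between QTL genotype classes, in phenotype SD units), or
#'   `NULL` for a no-QTL (null) genome.
#' @param h2 narrow-sense heritability of the phenotype, in `[0, 1]`.
#' @param pool_size lines per extreme pool.
#' @param depth_mean mean sequencing depth per pool per site (Poisson).
#' @param parent_depth_mean mean depth for the two parent samples.
#' @param seg_model `"1:1"` (marker heterozygous in the focal parent,
#'   homozygous-reference in the other; progeny segregate 1:1) or
#'   `"1:2:1"` (both parents heterozygous).
#' @param cM_per_Mb genetic map density used to link markers on the QTL
#'   chromosome to the QTL (Haldane map function).
#' @param error_rate symmetric per-read sequencing error rate applied to
#'   the allele draw (0 disables it and keeps expectations exact).
#' @param seed integer RNG seed applied at the start of [simulate_cross()].
#' @return an object of class `sim_config` (a validated list).
#' @seealso [simulate_cross()], [simulate_pool_reads()], [simulate_qtlseq_run()]
#' @export
#' @examples
#' cfg <- sim_config(chromosomes = c(chr1 = 2e6), marker_density = 50,
#'                   qtl = list(chrom = "chr1", pos = 1e6, effect = 1))
#' cfg
sim_config <- function(n_progeny = 284,
                       chromosomes = c(chr1 = 40e6, chr2 = 25e6, chr3 = 20e6),
                       marker_density = 100,
                       snp_fraction = 0.8,
                       qtl = list(chrom = "chr1", pos = 31e6, effect = 1),
                       h2 = 0.6,
                       pool_size = 30,
                       depth_mean = 40,
                       parent_depth_mean = 14,
                       seg_model = c("1:1", "1:2:1"),
                       cM_per_Mb = 3,
                       error_rate = 0,
                       seed = 1L) {
  seg_model <- match.arg(seg_model)
  stop_if_not_scalar_number(n_progeny, "n_progeny", min = 4)
  if (is.null(names(chromosomes)) || any(!nzchar(names(chromosomes))) ||
      anyDuplicated(names(chromosomes)) || any(chromosomes <= 0)) {
    stop("`chromosomes` must be a named vector of positive lengths with unique names",
         call. = FALSE)
  }
  stop_if_not_scalar_number(marker_density, "marker_density", min = 1e-12)
  stop_if_not_scalar_number(snp_fraction, "snp_fraction", min = 0, max = 1)
  stop_if_not_scalar_number(h2, "h2", min = 0, max = 1)
  stop_if_not_scalar_number(pool_size, "pool_size", min = 1)
  if (pool_size > n_progeny / 2) {
    stop("`pool_size` must not exceed n_progeny/2 (pools must be disjoint)",
         call. = FALSE)
  }
  stop_if_not_scalar_number(depth_mean, "depth_mean", min = 1e-9)
  stop_if_not_scalar_number(parent_depth_mean, "parent_depth_mean", min = 1e-9)
  stop_if_not_scalar_number(cM_per_Mb, "cM_per_Mb", min = 0)
  stop_if_not_scalar_number(error_rate, "error_rate", min = 0, max = 0.5)
  if (!is.null(qtl)) {
    if (!all(c("chrom", "pos", "effect") %in% names(qtl))) {
      stop("`qtl` must have elements chrom, pos, effect (or be NULL)", call. = FALSE)
    }
    if (!qtl$chrom %in% names(chromosomes)) {
      stop("qtl$chrom is not one of the configured chromosomes", call. = FALSE)
    }
    if (qtl$pos >= chromosomes[[qtl$chrom]]) {
      stop("qtl$pos must be smaller than its chromosome length", call. = FALSE)
    }
  }
  total_markers <- sum(round(chromosomes / 1e6 * marker_density))
  if (total_markers < 1) stop("configuration yields zero markers", call. = FALSE)
  structure(list(
    n_progeny = as.integer(n_progeny), chromosomes = chromosomes,
    marker_density = marker_density, snp_fraction = snp_fraction,
    qtl = qtl, h2 = h2, pool_size = as.integer(pool_size),
    depth_mean = depth_mean, parent_depth_mean = parent_depth_mean,
    seg_model = seg_model, cM_per_Mb = cM_per_Mb,
    error_rate = error_rate, seed = seed
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("QTL-seq simulation configuration\n")
  cat(sprintf("  progeny: %d  pools: 2 x %d  seg model: %s\n",
              x$n_progeny, x$pool_size, x$seg_model))
  cat(sprintf("  chromosomes: %s\n",
              paste(sprintf("%s (%.1f Mb)", names(x$chromosomes),
                            x$chromosomes / 1e6), collapse = ", ")))
  if (is.null(x$qtl)) cat("  QTL: none (null genome)\n")
  else cat(sprintf("  QTL: %s:%d  effect %.2f SD  h2 %.2f\n",
                   x$qtl$chrom, as.integer(x$qtl$pos), x$qtl$effect, x$h2))
  cat(sprintf("  markers: %.0f/Mb (%.0f%% SNP)  depth: %gx pools, %gx parents\n",
              x$marker_density, 100 * x$snp_fraction, x$depth_mean,
              x$parent_depth_mean))
  invisible(x)
}

haldane_r <- function(d_morgan) 0.5 * (1 - exp(-2 * d_morgan))

# draw marker positions on a 10-bp grid so that neighbouring ref alleles
# (deletions span up to 7 bp) can never overlap
draw_marker_table <- function(config) {
  snp_alt <- function(ref) {
    vapply(ref, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
  }
  rand_seq <- function(len) {
    vapply(len, function(l) paste(sample(c("A", "C", "G", "T"), l, replace = TRUE),
                                  collapse = ""), "")
  }
  out <- lapply(names(config$chromosomes), function(ch) {
    len <- config$chromosomes[[ch]]
    n <- round(len / 1e6 * config$marker_density)
    if (n < 1) return(NULL)
    slots <- max(floor(len / 10) - 1L, n)
    pos <- sort(sample.int(slots, n)) * 10L
    vtype <- ifelse(stats::runif(n) < config$snp_fraction, "SNP",
                    ifelse(stats::runif(n) < 0.5, "insertion", "deletion"))
    ref_base <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
    indel_len <- sample.int(6, n, replace = TRUE,
                            prob = 0.55 * 0.55^(0:5))  # short indels dominate
    ref <- ref_base
    alt <- ref_base
    is_snp <- vtype == "SNP"
    alt[is_snp] <- snp_alt(ref_base[is_snp])
    ins <- vtype == "insertion"
    alt[ins] <- paste0(ref_base[ins], rand_seq(indel_len[ins]))
    del <- vtype == "deletion"
    ref[del] <- paste0(ref_base[del], rand_seq(indel_len[del]))
    data.frame(chrom = ch, pos = pos, ref = ref, alt = alt, vtype = vtype,
               stringsAsFactors = FALSE)
  })
  mk <- do.call(rbind, out)
  mk$marker_id <- sprintf("M%06d", seq_len(nrow(mk)))
  mk[c("marker_id", "chrom", "pos", "ref", "alt", "vtype")]
}

# gamete matrix (n x m, 0/1): allele transmitted by one heterozygous parent,
# in coupling with its QTL allele q01 at recombination fraction r per marker
draw_gametes <- function(n, r, q01) {
  m <- length(r)
  flip <- matrix(stats::rbinom(n * m, 1L, rep(r, each = n)), n, m)
  if (is.null(q01)) return(flip)
  matrix(as.integer(xor(rep(q01, times = m), flip)), n, m)
}

#' Simulate an F1 mapping population with a planted QTL
#'
#' Draws marker positions and alleles, per-line genotypes under the
#' configured segregation model, and phenotypes. Under the `"1:1"`
#' pseudo-testcross model every marker is heterozygous in the focal (female)
#' parent and homozygous-reference in the other, so progeny dosages are 0/1
#' and the expected alternate-allele frequency at unlinked markers is 0.25.
#' Markers on the QTL chromosome are transmitted in coupling with the
#' high-value QTL allele at a recombination fraction given by the Haldane
#' map function and `cM_per_Mb`.
#'
#' The phenotype (in SD units) is `effect * q + polygene + environment`,
#' with the polygenic variance chosen so that the total genotypic variance
#' fraction equals `h2` and the total variance is 1. If a single QTL alone
#' would exceed `h2`, the genetic component is rescaled to variance `h2`
#' (so at `h2 = 0` the phenotype is independent of the QTL genotype).
#'
#' @param config a [sim_config()].
#' @return object of class `sim_truth`: list with `config`, `markers`
#'   (data.frame), `genotypes` (lines x markers dosage matrix), `phenotype`
#'   (named vector, SD units), `line_ids`, `qtl`.
#' @export
simulate_cross <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_progeny
  mk <- draw_marker_table(config)
  m <- nrow(mk)
  if (m < 1) stop("configuration yields zero markers", call. = FALSE)

  # recombination fraction to the QTL; 0.5 == unlinked
  r <- rep(0.5, m)
  if (!is.null(config$qtl)) {
    on_qtl_chrom <- mk$chrom == config$qtl$chrom
    d <- abs(mk$pos - config$qtl$pos) / 1e6 * config$cM_per_Mb / 100
    r[on_qtl_chrom] <- haldane_r(d[on_qtl_chrom])
  }

  if (config$seg_model == "1:1") {
    qf <- if (is.null(config$qtl)) NULL else stats::rbinom(n, 1L, 0.5)
    G <- draw_gametes(n, r, qf)
    q <- qf
    v_q <- 0.25
  } else {
    qf <- if (is.null(config$qtl)) NULL else stats::rbinom(n, 1L, 0.5)
    qm <- if (is.null(config$qtl)) NULL else stats::rbinom(n, 1L, 0.5)
    G <- draw_gametes(n, r, qf) + draw_gametes(n, r, qm)
    q <- if (is.null(config$qtl)) NULL else qf + qm
    v_q <- 0.5
  }

  h2 <- config$h2
  effect <- if (is.null(config$qtl)) 0 else config$qtl$effect
  qvar <- effect^2 * v_q
  if (is.null(q) || qvar == 0) {
    genetic <- sqrt(h2) * stats::rnorm(n)
    realized_effect <- 0
  } else if (qvar <= h2) {
    genetic <- effect * q + stats::rnorm(n, 0, sqrt(h2 - qvar))
    realized_effect <- effect
  } else {
    s <- sqrt(h2 / qvar)
    genetic <- s * effect * q
    realized_effect <- s * effect
  }
  y <- genetic + stats::rnorm(n, 0, sqrt(1 - h2))
  ids <- sprintf("L%03d", seq_len(n))
  names(y) <- ids
  rownames(G) <- ids
  colnames(G) <- mk$marker_id

  structure(list(
    config = config, markers = mk, genotypes = G, phenotype = y,
    line_ids = ids,
    qtl = if (is.null(config$qtl)) NULL else
      c(config$qtl, list(realized_effect = realized_effect))
  ), class = "sim_truth")
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf("sim_truth: %d lines, %d markers on %d chromosome(s)\n",
              length(x$line_ids), nrow(x$markers),
              length(unique(x$markers$chrom))))
  if (!is.null(x$qtl)) {
    cat(sprintf("  QTL %s:%d, realized class effect %.3f SD\n",
                x$qtl$chrom, as.integer(x$qtl$pos), x$qtl$realized_effect))
  } else cat("  no QTL (null genome)\n")
  invisible(x)
}

#' Select extreme phenotype pools
#'
#' Ranks lines by phenotype and returns the top and bottom `pool_size`
#' line ids (ties broken deterministically by line id).
#'
#' @param truth a `sim_truth` from [simulate_cross()].
#' @param pool_size lines per pool; defaults to the configured value.
#' @return list of class `pool_selection` with character vectors `large`
#'   and `small`.
#' @export
select_pools <- function(truth, pool_size = truth$config$pool_size) {
  stopifnot(inherits(truth, "sim_truth"))
  n <- length(truth$phenotype)
  if (2 * pool_size > n) {
    stop("pool_size * 2 exceeds the number of progeny", call. = FALSE)
  }
  if (any(is.na(truth$phenotype))) stop("phenotypes missing", call. = FALSE)
  ord <- order(-truth$phenotype, truth$line_ids)
  large <- truth$line_ids[ord][seq_len(pool_size)]
  ord2 <- order(truth$phenotype, truth$line_ids)
  small <- truth$line_ids[ord2][seq_len(pool_size)]
  structure(list(large = large, small = small), class = "pool_selection")
}

# pool alternate-allele frequency: mean dosage over pooled lines / 2 alleles
pool_alt_freq <- function(truth, ids) {
  ploidy_dosage_max <- 2  # dosage is counted out of 2 alleles in both models
  colMeans(truth$genotypes[ids, , drop = FALSE]) / ploidy_dosage_max
}

draw_sample_reads <- function(m, depth_mean, freq, error_rate) {
  dp <- stats::rpois(m, depth_mean)
  p <- freq * (1 - error_rate) + (1 - freq) * error_rate
  alt <- stats::rbinom(m, dp, p)
  list(ref = dp - alt, alt = alt)
}

#' Simulate pooled and parental read counts at every marker
#'
#' Per site and sample, depth is Poisson with the configured mean and the
#' alternate-read count is binomial with success probability equal to the
#' sample's true alternate-allele frequency (for a pool: the mean of the
#' pooled lines' dosages over 2 alleles; for a parent: 0.5 if heterozygous,
#' 0 otherwise), optionally perturbed by a symmetric error rate.
#'
#' @param truth a `sim_truth`.
#' @param pools a `pool_selection`; defaults to [select_pools()] on `truth`.
#' @param samples character(4) VCF sample names in the order female parent,
#'   male parent, large pool, small pool.
#' @return a `variant_sites` data.frame: `chrom, pos, ref, alt, vtype` plus
#'   `<sample>.ref` / `<sample>.alt` read-count columns; sample roles are
#'   kept in `attr(, "roles")`.
#' @export
simulate_pool_reads <- function(truth, pools = select_pools(truth),
                                samples = c("parent_female", "parent_male",
                                            "pool_large", "pool_small")) {
  stopifnot(inherits(truth, "sim_truth"), inherits(pools, "pool_selection"))
  stopifnot(length(samples) == 4, !anyDuplicated(samples))
  cfg <- truth$config
  m <- nrow(truth$markers)
  freq_f <- rep(0.5, m)                                   # focal parent het
  freq_m <- rep(if (cfg$seg_model == "1:2:1") 0.5 else 0, m)
  freqs <- list(freq_f, freq_m,
                pool_alt_freq(truth, pools$large),
                pool_alt_freq(truth, pools$small))
  depths <- c(cfg$parent_depth_mean, cfg$parent_depth_mean,
              cfg$depth_mean, cfg$depth_mean)
  sites <- truth$markers[c("chrom", "pos", "ref", "alt", "vtype")]
  for (k in seq_along(samples)) {
    rd <- draw_sample_reads(m, depths[k], freqs[[k]], cfg$error_rate)
    sites[[paste0(samples[k], ".ref")]] <- rd$ref
    sites[[paste0(samples[k], ".alt")]] <- rd$alt
  }
  attr(sites, "roles") <- stats::setNames(
    samples, c("parent_f", "parent_m", "pool_large", "pool_small"))
  class(sites) <- c("variant_sites", "data.frame")
  sites
}

#' Per-line phenotype table on trait scales
#'
#' Maps the latent SD-unit phenotype onto fruit-size trait scales (single
#' fruit weight in g, fruit length and diameter in mm) with realistic trait
#' correlations, and prepends the two parent lines with fixed trait means.
#' Fruit length/diameter share the latent size factor with loading 0.8.
#'
#' @param truth a `sim_truth`.
#' @param f1_scale list of `mean`/`sd` per trait used for the affine mapping.
#' @param parent_rows include `P_female`/`P_male` rows (role column flags them).
#' @return data.frame: `line_id, role, single_fruit_weight_g,
#'   fruit_length_mm, fruit_diameter_mm`.
#' @export
phenotype_table <- function(truth,
                            f1_scale = list(weight = c(10.5, 3.52),
                                            length = c(35.69, 5.31),
                                            diameter = c(23.83, 2.89)),
                            parent_rows = TRUE) {
  stopifnot(inherits(truth, "sim_truth"))
  z <- truth$phenotype
  n <- length(z)
  zl <- 0.8 * z + 0.6 * stats::rnorm(n)
  zd <- 0.8 * z + 0.6 * stats::rnorm(n)
  aff <- function(sc, zz) pmax(sc[1] + sc[2] * zz, 0.1 * sc[2])
  f1 <- data.frame(
    line_id = truth$line_ids, role = "F1",
    single_fruit_weight_g = round(aff(f1_scale$weight, z), 2),
    fruit_length_mm = round(aff(f1_scale$length, zl), 2),
    fruit_diameter_mm = round(aff(f1_scale$diameter, zd), 2),
    stringsAsFactors = FALSE)
  if (!parent_rows) return(f1)
  par <- data.frame(
    line_id = c("P_female", "P_male"),
    role = c("parent_f", "parent_m"),
    single_fruit_weight_g = c(11.40, 15.79),
    fruit_length_mm = c(35.78, 44.72),
    fruit_diameter_mm = c(24.83, 26.82),
    stringsAsFactors = FALSE)
  rbind(par, f1)
}

#' Run the full synthetic-data generator and optionally write a bundle
#'
#' Convenience wrapper: simulates the cross, selects pools, draws pooled
#' reads, simulates gene models (and, when requested, a genome sequence
#' carrying the marker reference alleles), builds the phenotype table, and
#' writes a self-contained input bundle (VCF + GFF3 + FASTA + phenotype TSV
#' + truth JSON) when `dir` is given. Fully deterministic for a fixed
#' `config$seed`.
#'
#' @param config a [sim_config()].
#' @param dir output directory, or `NULL` to skip writing.
#' @param genes_per_mb gene density for [simulate_genes()] (genes per Mb).
#' @param with_genome simulate and write the genome FASTA (needed for coding
#'   consequence annotation; costly for large chromosomes).
#' @return list with `truth`, `pools`, `sites`, `genes`, `genome`,
#'   `phenotypes` and, when written, `paths`.
#' @export
simulate_qtlseq_run <- function(config, dir = NULL, genes_per_mb = 15,
                                with_genome = !is.null(dir)) {
  truth <- simulate_cross(config)          # seeds the RNG stream
  pools <- select_pools(truth)
  sites <- simulate_pool_reads(truth, pools)
  genes <- simulate_genes(config$chromosomes, genes_per_mb = genes_per_mb)
  phenos <- phenotype_table(truth)
  genome <- if (with_genome) {
    simulate_genome(config$chromosomes, markers = truth$markers, genes = genes)
  }
  out <- list(truth = truth, pools = pools, sites = sites, genes = genes,
              genome = genome, phenotypes = phenos)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(
      vcf = file.path(dir, "variants.vcf"),
      gff3 = file.path(dir, "genes.gff3"),
      fasta = if (with_genome) file.path(dir, "genome.fa"),
      phenotypes = file.path(dir, "phenotypes.tsv"),
      truth = file.path(dir, "truth.json"))
    write_variant_vcf(sites, paths$vcf, contig_lengths = config$chromosomes)
    write_gff3(genes, paths$gff3)
    if (with_genome) Biostrings::writeXStringSet(genome, paths$fasta)
    write_tsv_plain(phenos, paths$phenotypes)
    truth_json <- list(
      seed = config$seed, seg_model = config$seg_model,
      qtl = truth$qtl, h2 = config$h2,
      pool_large = pools$large, pool_small = pools$small,
      n_progeny = config$n_progeny, n_markers = nrow(truth$markers))
    jsonlite::write_json(truth_json, paths$truth, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    out$paths <- paths
  }
  out
}
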
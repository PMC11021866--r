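# SNP-index / InDel-index / delta-index statistics, site filters,
# sliding-window genome scan against simulated null confidence intervals,
# and candidate-interval calling.

#' Compute per-site pool indices and the delta-index
#'
#' The index of a pool at a site is the fraction of its reads carrying the
#' non-reference allele, `alt / (ref + alt)`; it is missing (`NA`) at zero
#' depth. The delta-index is `index_large - index_small`.
#'
#' @param sites a `variant_sites` data.frame.
#' @param large,small VCF sample names of the two pools; default from the
#'   `roles` attribute.
#' @return an `index_records` data.frame: `chrom, pos, ref, alt, vtype,
#'   depth_large, depth_small, index_large, index_small, delta`.
#' @export
compute_indices <- function(sites,
                            large = attr(sites, "roles")[["pool_large"]],
                            small = attr(sites, "roles")[["pool_small"]]) {
  get2 <- function(s, which) {
    col <- paste0(s, ".", which)
    if (is.null(sites[[col]])) stop("missing sample column ", col, call. = FALSE)
    sites[[col]]
  }
  dl <- get2(large, "ref") + get2(large, "alt")
  ds <- get2(small, "ref") + get2(small, "alt")
  il <- ifelse(dl > 0, get2(large, "alt") / dl, NA_real_)
  is_ <- ifelse(ds > 0, get2(small, "alt") / ds, NA_real_)
  out <- data.frame(chrom = sites$chrom, pos = sites$pos, ref = sites$ref,
                    alt = sites$alt, vtype = sites$vtype,
                    depth_large = dl, depth_small = ds,
                    index_large = il, index_small = is_,
                    delta = il - is_, stringsAsFactors = FALSE)
  class(out) <- c("index_records", "data.frame")
  out
}

#' Filter index records (low-index / low-depth / missing sites)
#'
#' A record is dropped if and only if (a) both pool indices are below
#' `min_index`, or (b) both pool depths are below `min_depth`, or (c)
#' either index is missing. A site below threshold in only one pool is
#' retained. The operation is idempotent.
#'
#' @param records an `index_records` data.frame.
#' @param min_index index floor (default 0.3).
#' @param min_depth depth floor (default 7).
#' @return the retained records.
#' @export
filter_records <- function(records, min_index = 0.3, min_depth = 7) {
  drop <- (records$index_large < min_index & records$index_small < min_index) |
    (records$depth_large < min_depth & records$depth_small < min_depth) |
    is.na(records$index_large) | is.na(records$index_small)
  drop[is.na(drop)] <- TRUE
  out <- records[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# window frame for one chromosome: 0-based half-open [start, end);
# full windows start at multiples of `step` with start + window <= L, plus
# one truncated terminal window when L is not reached exactly
window_frame <- function(L, window, step) {
  if (L <= window) return(data.frame(start = 0, end = L))
  starts <- seq(0, L - window, by = step)
  ends <- starts + window
  if ((L - window) %% step != 0) {
    starts <- c(starts, (floor((L - window) / step) + 1) * step)
    ends <- c(ends, L)
  }
  data.frame(start = starts, end = ends)
}

harmonic_mean <- function(x) length(x) / sum(1 / x)

#' Sliding-window scan of the delta-index
#'
#' Windows of width `window` stepped every `step` bp along each chromosome
#' (0-based half-open; a final truncated window covers the chromosome end).
#' The window statistic is the unweighted arithmetic mean of the per-site
#' delta-index; windows without sites carry `NA`. A per-window depth
#' summary (mean or harmonic mean of per-site mean pool depths) keys the
#' confidence-interval lookup, and windows whose mean delta falls outside
#' the simulated null envelope at `level` are flagged significant when a
#' `ci` table is supplied.
#'
#' @param records filtered `index_records`.
#' @param chrom_lengths named vector of chromosome lengths (bp).
#' @param window,step window width and stride (bp); `window >= step > 0`.
#' @param ci optional `null_ci` table from [simulate_null_ci()].
#' @param level confidence level used for the `significant` flag (0.95 or
#'   0.99).
#' @param depth_stat `"mean"` or `"harmonic"` summary of per-site depths.
#' @param min_abs_delta optional absolute delta floor added to the
#'   significance rule.
#' @return a `window_scan` data.frame: `chrom, start, end, n_sites,
#'   mean_delta, mean_depth, ci95_lo, ci95_hi, ci99_lo, ci99_hi,
#'   significant`.
#' @export
sliding_window_scan <- function(records, chrom_lengths, window = 1e6,
                                step = 1e3, ci = NULL, level = 0.95,
                                depth_stat = c("mean", "harmonic"),
                                min_abs_delta = 0) {
  depth_stat <- match.arg(depth_stat)
  if (step <= 0 || window < step) {
    stop("need window >= step > 0", call. = FALSE)
  }
  out <- lapply(names(chrom_lengths), function(ch) {
    wf <- window_frame(chrom_lengths[[ch]], window, step)
    rec <- records[records$chrom == ch, , drop = FALSE]
    rec <- rec[order(rec$pos), , drop = FALSE]
    # site with 1-based position p lies in [start, end) iff start < p <= end
    cum_n <- c(0, seq_len(nrow(rec)))
    cs_delta <- c(0, cumsum(rec$delta))
    sited <- (rec$depth_large + rec$depth_small) / 2
    cs_depth <- c(0, cumsum(sited))
    cs_invd <- c(0, cumsum(1 / pmax(sited, 1e-9)))
    i_lo <- findInterval(wf$start, rec$pos)
    i_hi <- findInterval(wf$end, rec$pos)
    n <- i_hi - i_lo
    mean_delta <- ifelse(n > 0, (cs_delta[i_hi + 1] - cs_delta[i_lo + 1]) / n, NA)
    mean_depth <- if (depth_stat == "mean") {
      ifelse(n > 0, (cs_depth[i_hi + 1] - cs_depth[i_lo + 1]) / n, NA)
    } else {
      ifelse(n > 0, n / (cs_invd[i_hi + 1] - cs_invd[i_lo + 1]), NA)
    }
    data.frame(chrom = ch, start = wf$start, end = wf$end, n_sites = n,
               mean_delta = mean_delta, mean_depth = mean_depth,
               stringsAsFactors = FALSE)
  })
  scan <- do.call(rbind, out)
  scan$ci95_lo <- NA_real_
  scan$ci95_hi <- NA_real_
  scan$ci99_lo <- NA_real_
  scan$ci99_hi <- NA_real_
  scan$significant <- NA
  if (!is.null(ci)) {
    b <- lookup_ci(ci, scan$mean_depth)
    scan$ci95_lo <- b$lo95; scan$ci95_hi <- b$hi95
    scan$ci99_lo <- b$lo99; scan$ci99_hi <- b$hi99
    lo <- if (level >= 0.99) scan$ci99_lo else scan$ci95_lo
    hi <- if (level >= 0.99) scan$ci99_hi else scan$ci95_hi
    scan$significant <- !is.na(scan$mean_delta) &
      (scan$mean_delta < lo | scan$mean_delta > hi) &
      abs(scan$mean_delta) >= min_abs_delta
  }
  class(scan) <- c("window_scan", "data.frame")
  scan
}

#' Simulate null confidence intervals for the delta-index
#'
#' For each requested depth, repeatedly (i) draws two pools of `pool_size`
#' progeny under the no-QTL segregation model (`"1:1"`: dosage Bernoulli(1/2)
#' out of 2 alleles, null pool frequency centred on 0.25; `"1:2:1"`:
#' Binomial(2, 1/2) dosages, centred on 0.5), (ii) draws per-pool depths
#' (Poisson around the depth key by default, or fixed), (iii) samples
#' alternate reads binomially at the pool frequency, and (iv) computes the
#' delta-index. When `min_index`/`min_depth` are given (the default — the
#' same retention rule applied to the data), draws removed by the site
#' filter are discarded before taking quantiles, so the envelope is the
#' null distribution of the delta-index among *retained* sites. CI bounds
#' are the empirical `(1 +/- level)/2` quantiles.
#'
#' @param depths integer vector of mean per-pool depths to simulate.
#' @param pool_size lines per pool.
#' @param seg_model `"1:1"` or `"1:2:1"`.
#' @param n_sims simulated sites per depth (warned below 1000).
#' @param levels confidence levels (fixed grid 0.95 / 0.99 reported).
#' @param min_index,min_depth retention rule matching [filter_records()];
#'   set `min_index = NULL` to disable conditioning.
#' @param depth_model `"poisson"` (default; matches the read simulator) or
#'   `"fixed"`.
#' @param error_rate symmetric read error applied to the allele draw.
#' @return a `null_ci` data.frame: `depth, lo95, hi95, lo99, hi99,
#'   n_retained`.
#' @export
simulate_null_ci <- function(depths, pool_size = 30,
                             seg_model = c("1:1", "1:2:1"), n_sims = 10000,
                             levels = c(0.95, 0.99), min_index = 0.3,
                             min_depth = 7,
                             depth_model = c("poisson", "fixed"),
                             error_rate = 0) {
  seg_model <- match.arg(seg_model)
  depth_model <- match.arg(depth_model)
  if (n_sims < 1000) warning("n_sims < 1000: CI quantiles will be unstable")
  depths <- sort(unique(as.integer(depths)))
  one <- function(d) {
    draw_pool_freq <- function() {
      if (seg_model == "1:1") stats::rbinom(n_sims, pool_size, 0.5) / (2 * pool_size)
      else stats::rbinom(n_sims, 2 * pool_size, 0.5) / (2 * pool_size)
    }
    fl <- draw_pool_freq(); fs <- draw_pool_freq()
    dl <- if (depth_model == "poisson") stats::rpois(n_sims, d) else rep(d, n_sims)
    ds <- if (depth_model == "poisson") stats::rpois(n_sims, d) else rep(d, n_sims)
    padj <- function(p) p * (1 - error_rate) + (1 - p) * error_rate
    al <- stats::rbinom(n_sims, dl, padj(fl))
    as_ <- stats::rbinom(n_sims, ds, padj(fs))
    il <- ifelse(dl > 0, al / dl, NA_real_)
    is_ <- ifelse(ds > 0, as_ / ds, NA_real_)
    keep <- !(is.na(il) | is.na(is_))
    if (!is.null(min_index)) {
      keep <- keep & !((il < min_index & is_ < min_index) |
                         (dl < min_depth & ds < min_depth))
      keep[is.na(keep)] <- FALSE
    }
    delta <- (il - is_)[keep]
    q95 <- stats::quantile(delta, c(0.025, 0.975), names = FALSE)
    q99 <- stats::quantile(delta, c(0.005, 0.995), names = FALSE)
    data.frame(depth = d, lo95 = q95[1], hi95 = q95[2],
               lo99 = q99[1], hi99 = q99[2], n_retained = length(delta))
  }
  out <- do.call(rbind, lapply(depths, one))
  attr(out, "pool_size") <- pool_size
  attr(out, "seg_model") <- seg_model
  attr(out, "n_sims") <- n_sims
  class(out) <- c("null_ci", "data.frame")
  out
}

# nearest-depth lookup into a null_ci table
lookup_ci <- function(ci, depth) {
  ix <- pmax(findInterval(depth, ci$depth + 0.5) + 1L, 1L)
  ix <- pmin(ix, nrow(ci))
  ix[is.na(depth)] <- NA_integer_
  list(lo95 = ci$lo95[ix], hi95 = ci$hi95[ix],
       lo99 = ci$lo99[ix], hi99 = ci$hi99[ix])
}

#' Flag sites outside their per-depth null confidence interval
#'
#' Site-level analogue of the window rule: each record's delta-index is
#' compared against the simulated null envelope at the nearest depth key
#' (mean of the two pool depths, rounded).
#'
#' @param records filtered `index_records`.
#' @param ci a `null_ci` table covering the depth keys.
#' @param level 0.95 or 0.99.
#' @return logical vector, `TRUE` when outside the envelope.
#' @export
flag_outlier_sites <- function(records, ci, level = 0.95) {
  key <- round((records$depth_large + records$depth_small) / 2)
  b <- lookup_ci(ci, key)
  if (level >= 0.99) records$delta < b$lo99 | records$delta > b$hi99
  else records$delta < b$lo95 | records$delta > b$hi95
}

#' Merge significant windows into candidate intervals
#'
#' Overlapping or abutting significant windows are merged into maximal
#' intervals (no gap tolerance). Gene spans intersecting an interval are
#' attached and counted. Interval coordinates stay 0-based half-open; the
#' size in Mb is `(end - start) / 1e6` rounded half-up to 2 decimals.
#'
#' @param scan a `window_scan` with the `significant` flag set.
#' @param genes optional [gene_models()] for gene attachment.
#' @param marker_class label recorded in the `class` column
#'   (`"SNP"`, `"InDel"` or `"All"`).
#' @return a `candidate_intervals` data.frame: `chrom, start, end, size_mb,
#'   n_genes, genes, class`.
#' @export
call_intervals <- function(scan, genes = NULL, marker_class = "All") {
  sig <- scan[!is.na(scan$significant) & scan$significant, , drop = FALSE]
  if (!nrow(sig)) {
    out <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                      size_mb = numeric(), n_genes = integer(),
                      genes = character(), class = character(),
                      stringsAsFactors = FALSE)
    class(out) <- c("candidate_intervals", "data.frame")
    return(out)
  }
  gr <- GenomicRanges::GRanges(sig$chrom,
                               IRanges::IRanges(sig$start + 1, sig$end))
  merged <- GenomicRanges::reduce(gr)  # merges overlapping and abutting runs
  out <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(merged)),
    start = GenomicRanges::start(merged) - 1,
    end = as.numeric(GenomicRanges::end(merged)),
    stringsAsFactors = FALSE)
  out$size_mb <- round_half_up((out$end - out$start) / 1e6, 2)
  out$n_genes <- 0L
  out$genes <- ""
  if (!is.null(genes) && nrow(genes$genes)) {
    ggr <- GenomicRanges::GRanges(genes$genes$chrom,
                                  IRanges::IRanges(genes$genes$start,
                                                   genes$genes$end))
    ov <- suppressWarnings(GenomicRanges::findOverlaps(merged, ggr))
    if (length(ov)) {
      hits <- split(genes$genes$gene_id[S4Vectors::subjectHits(ov)],
                    S4Vectors::queryHits(ov))
      for (k in names(hits)) {
        i <- as.integer(k)
        out$n_genes[i] <- length(unique(hits[[k]]))
        out$genes[i] <- paste(sort(unique(hits[[k]])), collapse = ",")
      }
    }
  }
  out$class <- marker_class
  ord <- order(out$chrom, out$start)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("candidate_intervals", "data.frame")
  out
}

#' Combined All-index scan over SNP and InDel records
#'
#' Pools the (already filtered) SNP-index and InDel-index records and runs
#' the identical window/CI machinery on the union.
#'
#' @param snp_records,indel_records filtered `index_records`.
#' @inheritParams sliding_window_scan
#' @return a `window_scan` for the combined record set.
#' @export
all_index_scan <- function(snp_records, indel_records, chrom_lengths,
                           window = 1e6, step = 1e3, ci = NULL, level = 0.95,
                           depth_stat = "mean", min_abs_delta = 0) {
  shared <- intersect(names(snp_records), names(indel_records))
  both <- rbind(snp_records[shared], indel_records[shared])
  both <- both[order(both$chrom, both$pos), , drop = FALSE]
  rownames(both) <- NULL
  class(both) <- c("index_records", "data.frame")
  sliding_window_scan(both, chrom_lengths, window = window, step = step,
                      ci = ci, level = level, depth_stat = depth_stat,
                      min_abs_delta = min_abs_delta)
}
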
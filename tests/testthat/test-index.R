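# Index arithmetic, site filters, window scan, null CIs, interval calling.

# build index records directly (bypassing read counts)
rec_df <- function(chrom = "chr1", pos, delta = 0, il = NULL, is = NULL,
                   dl = 40, ds = 40) {
  n <- length(pos)
  if (is.null(il)) { il <- 0.25 + delta / 2; is <- 0.25 - delta / 2 }
  out <- data.frame(chrom = chrom, pos = as.integer(pos), ref = "A", alt = "G",
                    vtype = "SNP", depth_large = rep(dl, length.out = n),
                    depth_small = rep(ds, length.out = n),
                    index_large = rep(il, length.out = n),
                    index_small = rep(is, length.out = n))
  out$delta <- out$index_large - out$index_small
  class(out) <- c("index_records", "data.frame")
  out
}

sites_df <- function(lr, la, sr, sa) {
  out <- data.frame(chrom = "chr1", pos = seq_along(lr) * 100L, ref = "A",
                    alt = "G", vtype = "SNP",
                    pool_large.ref = lr, pool_large.alt = la,
                    pool_small.ref = sr, pool_small.alt = sa)
  attr(out, "roles") <- c(pool_large = "pool_large", pool_small = "pool_small")
  class(out) <- c("variant_sites", "data.frame")
  out
}

test_that("pool index and delta arithmetic", {
  s <- sites_df(lr = c(10, 20, 2, 0), la = c(10, 0, 18, 0),
                sr = c(10, 5, 18, 3), sa = c(10, 0, 2, 1))
  r <- compute_indices(s)
  expect_equal(r$index_large, c(0.5, 0, 0.9, NA))
  expect_equal(r$index_small, c(0.5, 0, 0.1, 0.25))
  expect_equal(r$delta, c(0, 0, 0.8, NA))
  expect_equal(r$depth_large, c(20, 20, 20, 0))
})

test_that("site filter drops exactly the specified records", {
  # enumerated truth table of boundary cases for the three filter clauses
  tab <- rbind(
    data.frame(il = 0.25, is = 0.28, dl = 50, ds = 50, keep = FALSE), # both idx low
    data.frame(il = 0.25, is = 0.90, dl = 50, ds = 50, keep = TRUE),  # one idx low
    data.frame(il = 0.90, is = 0.25, dl = 50, ds = 50, keep = TRUE),
    data.frame(il = 0.30, is = 0.29, dl = 50, ds = 50, keep = TRUE),  # 0.30 not < 0.3
    data.frame(il = 0.29, is = 0.29, dl = 50, ds = 50, keep = FALSE),
    data.frame(il = 0.50, is = 0.50, dl = 6,  ds = 6,  keep = FALSE), # both depths low
    data.frame(il = 0.50, is = 0.50, dl = 7,  ds = 6,  keep = TRUE),  # one depth low
    data.frame(il = 0.50, is = 0.50, dl = 6,  ds = 7,  keep = TRUE),
    data.frame(il = 0.50, is = 0.50, dl = 7,  ds = 7,  keep = TRUE),
    data.frame(il = NA,   is = 0.90, dl = 0,  ds = 50, keep = FALSE), # missing index
    data.frame(il = 0.90, is = NA,   dl = 50, ds = 0,  keep = FALSE),
    data.frame(il = 0.25, is = 0.25, dl = 6,  ds = 6,  keep = FALSE))
  r <- rec_df(pos = seq_len(nrow(tab)) * 10, il = tab$il, is = tab$is,
              dl = tab$dl, ds = tab$ds)
  kept <- filter_records(r)
  expect_equal(kept$pos, r$pos[tab$keep])
  # idempotent, never grows
  expect_equal(filter_records(kept), kept)
  expect_lte(nrow(kept), nrow(r))
})

test_that("window frame matches the count formula and truncation rule", {
  r <- rec_df(pos = 1)
  scan <- sliding_window_scan(r, c(chr1 = 2e6), window = 1e6, step = 1e3)
  expect_equal(nrow(scan), 1001)  # floor((L-W)/s) + 1 full windows
  expect_equal(scan$start[1], 0)
  expect_equal(scan$start[1001], 1e6)
  expect_true(all(scan$end - scan$start == 1e6))
  # chromosome shorter than the window: a single truncated window
  scan2 <- sliding_window_scan(r, c(chr1 = 5e5), window = 1e6, step = 1e3)
  expect_equal(nrow(scan2), 1)
  expect_equal(c(scan2$start, scan2$end), c(0, 5e5))
  # non-multiple remainder adds one terminal truncated window
  scan3 <- sliding_window_scan(r, c(chr1 = 2e6 + 500), window = 1e6, step = 1e3)
  expect_equal(nrow(scan3), 1002)
  expect_equal(scan3$end[1002], 2e6 + 500)
  expect_error(sliding_window_scan(r, c(chr1 = 1e6), window = 1e3, step = 1e4),
               "window >= step")
})

test_that("window means aggregate site deltas correctly", {
  # constant deltas: every non-empty window mean equals the constant
  r <- rec_df(pos = seq(1e4, 1.9e6, by = 1e4), delta = 0.4)
  scan <- sliding_window_scan(r, c(chr1 = 2e6), window = 1e6, step = 1e5)
  expect_true(all(abs(scan$mean_delta[scan$n_sites > 0] - 0.4) < 1e-12))
  # single site: exactly the windows overlapping it are non-empty
  r1 <- rec_df(pos = 1500500)
  scan1 <- sliding_window_scan(r1, c(chr1 = 2e6), window = 1e6, step = 1e3)
  hit <- scan1$n_sites > 0
  expect_true(all(scan1$start[hit] < 1500500 & 1500500 <= scan1$end[hit]))
  expect_equal(sum(hit), sum(scan1$start < 1500500 & 1500500 <= scan1$end))
  expect_true(all(is.na(scan1$mean_delta[!hit])))
})

test_that("null CI envelopes are symmetric-ish, nested and depth-monotone", {
  withr::local_seed(55)
  ci <- simulate_null_ci(c(7, 20, 40, 100), pool_size = 30, n_sims = 8000)
  # symmetry of the null: bounds mirror within Monte-Carlo error
  expect_true(all(abs(ci$lo95 + ci$hi95) < 0.06))
  # nesting: 99% envelope contains the 95% envelope
  expect_true(all(ci$lo99 <= ci$lo95 & ci$hi99 >= ci$hi95))
  # monotone width in depth: depth 7 wider than depth 100
  w <- ci$hi95 - ci$lo95
  expect_gt(w[ci$depth == 7], w[ci$depth == 100])
  expect_true(all(diff(w) < 0))
  expect_warning(simulate_null_ci(40, n_sims = 500), "n_sims")
})

test_that("swapping pool labels negates deltas and reflects significance", {
  withr::local_seed(66)
  cfg <- small_sim_config(seed = 66)
  sites <- simulate_pool_reads(simulate_cross(cfg))
  fwd <- filter_records(compute_indices(sites))
  rev <- filter_records(compute_indices(sites, large = "pool_small",
                                        small = "pool_large"))
  expect_equal(rev$delta, -fwd$delta)
  sym_ci <- data.frame(depth = 1:200, lo95 = -0.25, hi95 = 0.25,
                       lo99 = -0.35, hi99 = 0.35)
  class(sym_ci) <- c("null_ci", "data.frame")
  s1 <- sliding_window_scan(fwd, cfg$chromosomes, ci = sym_ci)
  s2 <- sliding_window_scan(rev, cfg$chromosomes, ci = sym_ci)
  expect_equal(s2$mean_delta, -s1$mean_delta)
  expect_equal(s2$significant, s1$significant)
})

test_that("interval merging and sizes", {
  scan <- data.frame(chrom = "chr1",
                     start = c(0, 0.5e6, 3e6), end = c(1e6, 1.5e6, 4e6),
                     n_sites = 10, mean_delta = 0.5, mean_depth = 40,
                     significant = c(TRUE, TRUE, FALSE))
  iv <- call_intervals(scan, marker_class = "SNP")
  expect_equal(nrow(iv), 1)
  expect_equal(c(iv$start, iv$end), c(0, 1.5e6))
  expect_equal(iv$size_mb, 1.5)
  # abutting windows merge, detached significant windows stay separate
  scan$significant[3] <- TRUE
  iv2 <- call_intervals(scan)
  expect_equal(nrow(iv2), 2)
  # the reported size of a 30.72-32.23 Mb interval is 1.51 Mb
  scan3 <- data.frame(chrom = "chr1", start = c(30.72e6, 31.23e6),
                      end = c(31.72e6, 32.23e6), n_sites = 5,
                      mean_delta = 0.5, mean_depth = 40, significant = TRUE)
  iv3 <- call_intervals(scan3)
  expect_equal(iv3$size_mb, 1.51)
  # no significant windows -> empty set
  scan$significant <- FALSE
  expect_equal(nrow(call_intervals(scan)), 0)
})

test_that("intervals attach and count overlapping genes", {
  gm <- gene_models(
    data.frame(gene_id = c("g1", "g2", "g3"), chrom = "chr1",
               strand = "+", start = c(100L, 5000L, 2000000L),
               end = c(400L, 6000L, 2000300L)),
    data.frame(gene_id = c("g1", "g2", "g3"), chrom = "chr1",
               strand = "+", start = c(100L, 5000L, 2000000L),
               end = c(399L, 5999L, 2000299L), exon_rank = 1L))
  scan <- data.frame(chrom = "chr1", start = 0, end = 1e4, n_sites = 3,
                     mean_delta = 0.6, mean_depth = 40, significant = TRUE)
  iv <- call_intervals(scan, genes = gm)
  expect_equal(iv$n_genes, 2L)
  expect_equal(iv$genes, "g1,g2")
})

test_that("All-index scan equals SNP scan when InDels are absent, counts add", {
  cfg <- small_sim_config(seed = 77)
  sites <- simulate_pool_reads(simulate_cross(cfg))
  snp <- filter_records(compute_indices(sites[sites$vtype == "SNP", ]))
  ind <- filter_records(compute_indices(sites[sites$vtype != "SNP", ]))
  empty <- ind[0, ]
  a0 <- all_index_scan(snp, empty, cfg$chromosomes)
  s0 <- sliding_window_scan(snp, cfg$chromosomes)
  expect_equal(a0, s0)
  # disjoint site sets: window site counts add
  a1 <- all_index_scan(snp, ind, cfg$chromosomes)
  s1 <- sliding_window_scan(ind, cfg$chromosomes)
  expect_equal(a1$n_sites, s0$n_sites + s1$n_sites)
})

test_that("site-level calibration: ~5% of null filtered sites fall outside", {
  # moderate-size replica of the genome-scale check (seeded)
  cfg <- sim_config(chromosomes = c(chr1 = 8e6), marker_density = 1500,
                    qtl = NULL, seed = 88)
  rec <- filter_records(compute_indices(simulate_pool_reads(simulate_cross(cfg))))
  keys <- sort(unique(round((rec$depth_large + rec$depth_small) / 2)))
  withr::local_seed(89)
  ci <- simulate_null_ci(keys, pool_size = 30, n_sims = 8000)
  frac <- mean(flag_outlier_sites(rec, ci, 0.95))
  expect_gt(frac, 0.03)
  expect_lt(frac, 0.07)
})
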
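# Generator: segregation expectations, heritability contract, pools,
# read model, VCF round trip, determinism.

test_that("configuration invariants are enforced", {
  expect_error(sim_config(h2 = 1.2), "h2")
  expect_error(sim_config(h2 = -0.1), "h2")
  expect_error(sim_config(pool_size = 200, n_progeny = 100), "pool_size")
  expect_error(sim_config(depth_mean = 0), "depth_mean")
  expect_error(sim_config(qtl = list(chrom = "chr1", pos = 99e6, effect = 1)),
               "chromosome length")
  expect_error(sim_config(qtl = list(chrom = "nope", pos = 1, effect = 1)),
               "chromosomes")
  expect_error(sim_config(chromosomes = c(chr1 = 1e3), marker_density = 0.1,
                          qtl = NULL),
               "zero markers")
})

test_that("1:1 pseudo-testcross markers segregate as expected", {
  cfg <- sim_config(chromosomes = c(chr1 = 5e5, chr2 = 5e5),
                    marker_density = 400, qtl = NULL,
                    n_progeny = 200, seed = 5)
  truth <- simulate_cross(cfg)
  expect_true(all(truth$genotypes %in% 0:1))
  # alternate-allele frequency at unlinked markers: dosage 1 of 2 alleles in
  # half the lines -> 0.25
  af <- mean(truth$genotypes) / 2
  expect_equal(af, 0.25, tolerance = 0.02)
  # 1:2:1: both parents heterozygous, dosages 0/1/2, frequency 0.5
  cfg2 <- sim_config(chromosomes = c(chr1 = 5e5), marker_density = 400,
                     qtl = NULL, n_progeny = 200, seg_model = "1:2:1",
                     seed = 6)
  truth2 <- simulate_cross(cfg2)
  expect_true(all(truth2$genotypes %in% 0:2))
  expect_equal(mean(truth2$genotypes) / 2, 0.5, tolerance = 0.02)
})

test_that("heritability scales the QTL signal as configured", {
  # h2 = 0: phenotype independent of the QTL genotype
  cfg0 <- sim_config(chromosomes = c(chr1 = 1e6), marker_density = 20,
                     qtl = list(chrom = "chr1", pos = 5e5, effect = 1),
                     h2 = 0, n_progeny = 284, seed = 7)
  t0 <- simulate_cross(cfg0)
  expect_equal(t0$qtl$realized_effect, 0)
  # class difference ~ effect at h2 = 0.6, effect = 1 SD (Monte-Carlo error
  # ~ 2 * sqrt(1 - effect^2/4) / sqrt(n) ~ 0.10)
  cfg1 <- sim_config(seed = 8)
  t1 <- simulate_cross(cfg1)
  # recover the QTL genotype from a marker at the QTL position distance ~ 0
  near <- which(t1$markers$chrom == "chr1" &
                  abs(t1$markers$pos - 31e6) < 2e4)[1]
  g <- t1$genotypes[, near]
  diff <- mean(t1$phenotype[g == 1]) - mean(t1$phenotype[g == 0])
  expect_equal(diff, 1, tolerance = 0.35)
  expect_equal(stats::var(t1$phenotype), 1, tolerance = 0.25)
})

test_that("pool selection is a deterministic extreme ranking", {
  G <- matrix(0L, 10, 3)
  tr <- fake_truth(phenotype = 1:10, genotypes = G)
  p <- select_pools(tr, pool_size = 2)
  expect_equal(p$large, c("L010", "L009"))
  expect_equal(p$small, c("L001", "L002"))
  # ties broken by line id, pools still disjoint
  tr2 <- fake_truth(phenotype = rep(1, 10), genotypes = G)
  p2 <- select_pools(tr2, pool_size = 3)
  expect_equal(p2$large, c("L001", "L002", "L003"))
  expect_equal(p2$small, c("L001", "L002", "L003"))
  expect_error(select_pools(tr, pool_size = 6), "exceeds")
  # study design: 284 lines, 30 + 30 pooled lines, disjoint
  cfg <- sim_config(chromosomes = c(chr1 = 2e5), marker_density = 50, seed = 2,
                    qtl = NULL)
  p3 <- select_pools(simulate_cross(cfg))
  expect_length(unique(c(p3$large, p3$small)), 60)
  expect_length(intersect(p3$large, p3$small), 0)
})

test_that("pooled read counts follow the binomial read model", {
  withr::local_seed(30)
  m <- 4000
  # all pooled lines carry dosage 0 -> alt reads are all zero
  tr0 <- fake_truth(phenotype = 1:20, genotypes = matrix(0L, 20, m))
  s0 <- simulate_pool_reads(tr0, select_pools(tr0, 5))
  expect_true(all(s0$pool_large.alt == 0))
  expect_true(all(s0$pool_small.alt == 0))
  # all lines dosage 1 (frequency 0.5) at depth ~20 -> mean alt reads ~10
  tr1 <- fake_truth(phenotype = 1:20, genotypes = matrix(1L, 20, m))
  tr1$config$depth_mean <- 20
  s1 <- simulate_pool_reads(tr1, select_pools(tr1, 5))
  expect_equal(mean(s1$pool_large.alt), 10, tolerance = 0.25)
  # unlinked 1:1 markers: both pool indices ~ 0.25, delta ~ 0
  cfg <- sim_config(chromosomes = c(chr1 = 2e6), marker_density = 2000,
                    qtl = NULL, seed = 31)
  tr <- simulate_cross(cfg)
  ss <- simulate_pool_reads(tr)
  rec <- compute_indices(ss)
  expect_equal(mean(rec$index_large, na.rm = TRUE), 0.25, tolerance = 0.01)
  expect_equal(mean(rec$index_small, na.rm = TRUE), 0.25, tolerance = 0.01)
  expect_equal(mean(rec$delta, na.rm = TRUE), 0, tolerance = 0.01)
})

test_that("written VCF round-trips the allele-depth matrix exactly", {
  dir <- withr::local_tempdir()
  cfg <- small_sim_config(seed = 44)
  run <- simulate_qtlseq_run(cfg, dir = dir, with_genome = FALSE)
  back <- read_variant_sites(file.path(dir, "variants.vcf"),
                             roles = attr(run$sites, "roles"))
  ord <- order(match(run$sites$chrom, names(cfg$chromosomes)), run$sites$pos)
  cols <- grep("\\.(ref|alt)$", names(run$sites), value = TRUE)
  expect_equal(unname(as.matrix(back[cols])),
               unname(as.matrix(run$sites[ord, cols])))
  expect_equal(back$ref, run$sites$ref[ord])
  expect_equal(back$alt, run$sites$alt[ord])
  expect_equal(back$vtype, run$sites$vtype[ord])
})

test_that("identical seeds give identical bundles", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  cfg <- small_sim_config(seed = 99)
  simulate_qtlseq_run(cfg, dir = d1, with_genome = FALSE)
  simulate_qtlseq_run(cfg, dir = d2, with_genome = FALSE)
  for (f in list.files(d1)) {
    expect_equal(unname(tools::md5sum(file.path(d1, f))),
                 unname(tools::md5sum(file.path(d2, f))), label = f)
  }
})

test_that("null genome-wide mean delta is within 3 standard errors of 0", {
  cfg <- sim_config(chromosomes = c(chr1 = 4e6, chr2 = 4e6),
                    marker_density = 1500, qtl = NULL, seed = 12)
  rec <- filter_records(compute_indices(simulate_pool_reads(simulate_cross(cfg))))
  se <- stats::sd(rec$delta) / sqrt(nrow(rec))
  expect_lt(abs(mean(rec$delta)), 3 * se)
})
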
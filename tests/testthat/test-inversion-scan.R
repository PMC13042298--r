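test_that("heterozygote-excess exact test matches a resampling oracle", {
  eh <- excess_het_test(0, 200, 0)
  expect_gt(eh$phred, 54.69)
  # the conditional distribution sums to 1 and the MC oracle agrees
  for (cs in list(c(5, 10, 5), c(2, 16, 2), c(8, 4, 8))) {
    p <- excess_het_test(cs[1], cs[2], cs[3])$p_value
    p_mc <- het_excess_mc(cs[1], cs[2], cs[3], reps = 20000, seed = 4)
    expect_lt(abs(p - p_mc), 3 * sqrt(p_mc * (1 - p_mc) / 20000) + 1e-3)
  }
  expect_equal(excess_het_test(10, 0, 10)$p_value, 1)
})

test_that("genotype masking applies DP/GQ, MAF, depth and ExcessHet rules", {
  n <- 40
  set.seed(6)
  geno <- rbind(ok = rbinom(n, 2, 0.4),
                lowmaf = rep(0L, n),
                allhet = rep(1L, n),
                tri = rbinom(n, 2, 0.4),
                deep = rbinom(n, 2, 0.4))
  sites <- data.frame(chrom = "LG1", pos = 1:5 * 1000,
                      id = rownames(geno),
                      biallelic = c(TRUE, TRUE, TRUE, FALSE, TRUE))
  dp <- matrix(20, 5, n); gq <- matrix(99, 5, n)
  dp[1, 1] <- 5                        # one genotype below DP 8
  gq[1, 2] <- 10                       # one below GQ 20
  dp[5, ] <- 200                       # site above mean + 1 SD
  gm <- geno_matrix(geno, sites, dp = dp, gq = gq)
  out <- mask_genotypes(gm)
  expect_true(is.na(out$geno["ok", 1]))
  expect_true(is.na(out$geno["ok", 2]))
  expect_false("tri" %in% out$sites$id)      # non-biallelic
  expect_false("lowmaf" %in% out$sites$id)   # MAF below floor
  expect_false("allhet" %in% out$sites$id)   # heterozygote excess
  expect_false("deep" %in% out$sites$id)     # depth cap
  expect_true("ok" %in% out$sites$id)
  d <- attr(out, "dropped")
  expect_equal(unname(d["non_biallelic"]), 1L)
  expect_equal(unname(d["excess_het"]), 1L)
  gm2 <- geno_matrix(geno, sites)
  expect_warning(mask_genotypes(gm2), "DP/GQ")
})

test_that("PCA genotyping recovers fixed-difference arrangements and flags nulls", {
  inv <- region_set("LG1", 2e6, 5e6, derived_freq = 0.4, id = "i1")
  lay <- simulate_genome(c(LG1 = 8e6), c(LG1 = 50), inversions = inv,
                         markers_per_lg = 200, seed = 61)
  pop <- simulate_population(lay, n = 120, divergence = 1, seed = 62)
  ins <- pop$site_freqs$inv == 1
  pg <- pca_genotype(subset_geno(pop$genotypes, sites = ins))
  expect_false(pg$ambiguous)
  truth <- pop$inv_truth[, 1]
  acc <- max(mean(pg$genotype == truth), mean(pg$genotype == 2L - truth))
  expect_equal(acc, 1)            # perfect separation by construction
  # no divergence: ambiguous
  pop0 <- simulate_population(lay, n = 120, divergence = 0, seed = 63)
  pg0 <- pca_genotype(subset_geno(pop0$genotypes, sites = ins))
  expect_true(pg0$ambiguous)
  expect_error(pca_genotype(subset_geno(pop$genotypes, sites = ins,
                                        individuals = 1:2)), "3 individuals")
  expect_error(pca_genotype(subset_geno(pop$genotypes, sites = 1:3)), "10 usable")
})

test_that("windowed Fst equals the independent per-site ANOVA oracle", {
  # toy: 10 vs 10 individuals, freq 0.9 vs 0.1 at one SNP
  set.seed(71)
  gA <- rbinom(10, 2, 0.9); gB <- rbinom(10, 2, 0.1)
  gm <- geno_matrix(matrix(c(gA, gB), 1), data.frame(chrom = "LG1", pos = 500L))
  expect_equal(site_fst(gm, 1:10, 11:20), wc_fst_anova(gA, gB),
               tolerance = 1e-12)
  # random sites with missingness: oracle equivalence per site
  for (i in 1:20) {
    gA <- rbinom(15, 2, runif(1, .1, .9)); gB <- rbinom(12, 2, runif(1, .1, .9))
    gA[sample(15, 2)] <- NA
    if (length(unique(c(gA, gB)[!is.na(c(gA, gB))])) == 1) next
    gm <- geno_matrix(matrix(c(gA, gB), 1),
                      data.frame(chrom = "LG1", pos = 500L))
    f <- site_fst(gm, 1:15, 16:27)
    if (is.na(f)) next
    expect_equal(f, wc_fst_anova(gA, gB), tolerance = 1e-12)
  }
  # fixed differences at every SNP: Fst = 1 in every window
  g <- matrix(c(rep(0L, 50), rep(2L, 50)), 5, 20)
  gm1 <- geno_matrix(g, data.frame(chrom = "LG1", pos = 1:5 * 1e4))
  tr <- windowed_fst(gm1, 1:10, 11:20)
  expect_true(all(abs(tr$fst[tr$n_snps > 0] - 1) < 1e-12))
  # a window holding exactly one SNP equals the site value
  one <- windowed_fst(gm, 1:15, 16:27, window_bp = 600, step_bp = 600)
  expect_equal(one$fst[1], site_fst(gm, 1:15, 16:27), tolerance = 1e-12)
  # invariant to individual order within groups
  gmx <- geno_matrix(g, data.frame(chrom = "LG1", pos = 1:5 * 1e4))
  t1 <- windowed_fst(gmx, 1:10, 11:20)
  t2 <- windowed_fst(gmx, sample(1:10), sample(11:20))
  expect_equal(t1$fst, t2$fst)
  expect_error(windowed_fst(gmx, 1, 2:20), ">= 2 individuals")
})

test_that("identical groups give near-zero Fst", {
  set.seed(81)
  p <- runif(50, 0.2, 0.8)
  g <- matrix(rbinom(50 * 200, 2, rep(p, 200)), 50, 200)
  gm <- geno_matrix(g, data.frame(chrom = "LG1", pos = seq_len(50) * 1000))
  tr <- windowed_fst(gm, 1:100, 101:200, window_bp = 5e4, step_bp = 5e4)
  expect_lt(abs(tr$fst[1]), 0.02)
})

test_that("boundary calling walks runs, merges short gaps, handles extremes", {
  tr <- data.frame(chrom = "LG1", start = seq(0, 6e5, 1e5),
                   end = seq(0, 6e5, 1e5) + 1e5,
                   fst = c(0.02, 0.05, 0.30, 0.40, 0.35, 0.10, 0.05), n_snps = 5)
  b <- call_boundaries(tr, 0.15, 3)
  expect_equal(b$start, 2e5)
  expect_equal(b$end, 5e5)
  # invariant to prepending/appending sub-threshold windows
  pre <- data.frame(chrom = "LG1", start = c(-2e5, -1e5) + 0,
                    end = c(-1e5, 0), fst = c(0.01, 0.02), n_snps = 5)
  pre$start <- c(-2e5, -1e5)
  tr2 <- rbind(pre, tr)
  tr2$start <- tr2$start + 2e5; tr2$end <- tr2$end + 2e5  # keep coords valid
  b2 <- call_boundaries(tr2, 0.15, 3)
  expect_equal(b2$end - b2$start, b$end - b$start)
  # all below / all above
  expect_equal(nrow(call_boundaries(transform(tr, fst = 0.05))), 0)
  ball <- call_boundaries(transform(tr, fst = 0.5))
  expect_equal(ball$start, 0)
  expect_equal(ball$end, 7e5)
  # two qualifying runs separated by a short gap merge into one region
  fst <- c(.3, .3, .3, .05, .3, .3, .3)
  trm <- data.frame(chrom = "LG1", start = seq(0, 6e5, 1e5),
                    end = seq(0, 6e5, 1e5) + 1e5, fst = fst, n_snps = 5)
  bm <- call_boundaries(trm, 0.15, 3)
  expect_equal(nrow(bm), 1)
  expect_equal(c(bm$start, bm$end), c(0, 7e5))
  expect_error(call_boundaries(tr[0, ]), "empty")
})

test_that("LD screening thins deterministically and finds fixed-difference blocks", {
  # duplicated SNP column: r2 = 1
  set.seed(91)
  v <- rbinom(100, 2, 0.5)
  g <- rbind(v, v)
  gm <- geno_matrix(g, data.frame(chrom = "LG1", pos = c(1000, 25000),
                                  id = c("s1", "s2")))
  ld <- ld_screen(gm, thin_bp = 1e4, maf_min = 0.1)
  expect_equal(ld$r2[1, 2], 1, tolerance = 1e-12)
  # independent SNPs: mean off-diagonal r2 about 1/n
  n <- 200
  g2 <- matrix(rbinom(40 * n, 2, 0.5), 40, n)
  gm2 <- geno_matrix(g2, data.frame(chrom = "LG1", pos = seq_len(40) * 1.1e4))
  ld2 <- ld_screen(gm2, maf_min = 0.1)
  off <- ld2$r2[upper.tri(ld2$r2)]
  se <- sqrt(2) / n / sqrt(length(off))   # var(r2) ~ 2/n^2 under independence
  expect_lt(abs(mean(off) - 1 / n), 5 * se + 2e-3)
  expect_equal(nrow(ld2$blocks), 0)
  # fixed-difference inversion: a block overlapping truth appears
  inv <- region_set("LG1", 2e6, 5e6, derived_freq = 0.4, id = "i1")
  lay <- simulate_genome(c(LG1 = 8e6), c(LG1 = 50), inversions = inv,
                         markers_per_lg = 400, seed = 92)
  pop <- simulate_population(lay, n = 150, divergence = 1, seed = 93)
  ld3 <- ld_screen(pop$genotypes)
  expect_gt(nrow(ld3$blocks), 0)
  expect_true(any(ld3$blocks$start < 5e6 & ld3$blocks$end > 2e6))
  # fewer than 2 kept SNPs: empty outputs
  ld4 <- ld_screen(subset_geno(gm2, sites = 1))
  expect_equal(nrow(ld4$blocks), 0)
})
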
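test_that("genome layouts are deterministic and carry a linear truth map", {
  lay1 <- toy_layout(seed = 3)
  lay2 <- toy_layout(seed = 3)
  expect_identical(lay1, lay2)
  lay3 <- toy_layout(seed = 4)
  expect_false(identical(lay1$markers, lay3$markers))

  # uniform 5 cM/Mb over 10 Mb: truth map is exactly linear
  lay <- simulate_genome(c(LG1 = 1e7), c(LG1 = 50), markers_per_lg = 50, seed = 1)
  expect_equal(truth_cM(lay, "LG1", 1e7), 50)
  expect_equal(truth_cM(lay, "LG1", 4e6), 20)
  expect_equal(truth_bp(lay, "LG1", 25), 5e6)
})

test_that("invalid inversion geometry is rejected", {
  inv_end <- region_set("LG1", 7e6, 8e6, derived_freq = 0.5)
  expect_error(toy_layout(inv = inv_end), "inside their LG")
  inv_ovl <- region_set(c("LG1", "LG1"), c(1e6, 2e6), c(3e6, 4e6),
                        derived_freq = 0.5)
  expect_error(toy_layout(inv = inv_ovl), "overlap")
  expect_silent(lay <- toy_layout(inv = inv_ovl, allow_overlap = TRUE))
  expect_error(simulate_genome(c(LG1 = -1), c(LG1 = 10)))
})

test_that("TE coverage inside inversions matches density x multiplier", {
  # base density 0.3, multiplier 0.5 inside a 2-Mb inversion: expected
  # inside coverage 0.15 of 2 Mb = 0.3 Mb; Monte-Carlo mean over 100 seeds
  inv <- region_set("LG1", 3e6, 5e6, derived_freq = 0.5, id = "inv1")
  inside <- vapply(1:100, function(s) {
    lay <- simulate_genome(c(LG1 = 1e7), c(LG1 = 50), inversions = inv,
                           markers_per_lg = 10, te_density = 0.3,
                           te_inversion_mult = 0.5, feature_bp = 1000, seed = s)
    te <- lay$te_track
    sum(pmax(0, pmin(te$end, 5e6) - pmax(te$start, 3e6)))
  }, numeric(1))
  # 2000 chunks/seed x 100 seeds at p = 0.15: binomial SE of the mean
  se <- sqrt(0.15 * 0.85 / (2000 * 100)) * 2e6
  expect_lt(abs(mean(inside) - 0.3e6), 3 * se)
})

test_that("crossover counts follow the Poisson law of the map length", {
  # 1 LG of 1 Morgan, no interference, 2000 meioses
  lay <- simulate_genome(c(LG1 = 1e7), c(LG1 = 100), markers_per_lg = 50,
                         seed = 2)
  cfg <- sim_config(n_families = 1L, offspring = 1000L, error_rate = 0,
                    missing_rate = 0, seed = 11)
  fam <- simulate_family(lay, cfg, 1)
  # 1000 offspring x 2 parents = 2000 meioses
  per_meiosis <- table(factor(paste(fam$crossovers$offspring_id,
                                    fam$crossovers$parent),
                              levels = outer(unique(fam$pedigree$id[-(1:2)]),
                                             c("father", "mother"),
                                             paste)))
  counts <- as.numeric(per_meiosis)
  expect_equal(length(counts), 2000)
  se_mean <- sqrt(1 / 2000)
  expect_lt(abs(mean(counts) - 1), 3 * se_mean)
  # Poisson: variance = mean; SE of the sample variance ~ sqrt(2/n) + skew term
  expect_lt(abs(stats::var(counts) - 1), 0.2)
})

test_that("heterokaryotype inversions receive zero crossovers, homokaryotypes do not", {
  inv <- region_set(c("LG1", "LG2"), c(2e6, 2e6), c(6e6, 6e6),
                    derived_freq = 0.5, id = c("i1", "i2"))
  lay <- toy_layout(n_lg = 2, cm = 80, inv = inv, seed = 5)
  cfg <- sim_config(n_families = 1L, offspring = 150L, error_rate = 0,
                    missing_rate = 0, seed = 9,
                    parent_karyotypes = list(rbind(father = c(1L, 0L),
                                                   mother = c(2L, 1L))))
  fam <- simulate_family(lay, cfg, 1)
  co <- fam$crossovers
  in_inv <- function(p, lg) sum(co$parent == p & co$lg == lg &
                                  co$pos >= 2e6 & co$pos < 6e6)
  expect_identical(in_inv("father", "LG1"), 0L)  # het at i1
  expect_identical(in_inv("mother", "LG2"), 0L)  # het at i2
  expect_gt(in_inv("mother", "LG1"), 0L)         # hom: unsuppressed
  expect_gt(in_inv("father", "LG2"), 0L)
  # suppression toggle restores events in heterokaryotype inversions
  cfg0 <- sim_config(n_families = 1L, offspring = 150L, error_rate = 0,
                     missing_rate = 0, seed = 9, suppression = FALSE,
                     parent_karyotypes = cfg$parent_karyotypes)
  fam0 <- simulate_family(lay, cfg0, 1)
  co0 <- fam0$crossovers
  expect_gt(sum(co0$parent == "father" & co0$lg == "LG1" &
                  co0$pos >= 2e6 & co0$pos < 6e6), 0L)
})

test_that("with no error or missingness, genotypes reconstruct from transmissions", {
  lay <- toy_layout(seed = 13)
  cfg <- sim_config(n_families = 1L, offspring = 30L, error_rate = 0,
                    missing_rate = 0, seed = 21)
  fam <- simulate_family(lay, cfg, 1)
  g <- fam$genotypes$geno
  mi <- fam$marker_info
  tr <- fam$transmissions
  gF <- g[, "F1_father"]; gM <- g[, "F1_mother"]
  for (off in unique(tr$offspring_id)) {
    trf <- tr[tr$offspring_id == off & tr$parent == "father", ]
    trm <- tr[tr$offspring_id == off & tr$parent == "mother", ]
    hF <- trf$hap[match(mi$id, trf$marker_id)]
    hM <- trm$hap[match(mi$id, trm$marker_id)]
    aF <- ifelse(mi$type %in% c("paternal", "both"), hF, gF / 2)
    aM <- ifelse(mi$type %in% c("maternal", "both"), hM, gM / 2)
    expect_equal(unname(g[, off]), as.integer(aF + aM))
  }
})

test_that("population panels obey Hardy-Weinberg and the divergence model", {
  inv <- region_set("LG1", 2e6, 5e6, derived_freq = 0.3, id = "inv1")
  lay <- simulate_genome(c(LG1 = 8e6), c(LG1 = 50), inversions = inv,
                         markers_per_lg = 30, seed = 17)
  pop <- simulate_population(lay, n = 10000, divergence = 0.4, seed = 23)
  counts <- table(factor(pop$inv_truth[, 1], levels = 0:2)) / 10000
  expected <- c(0.49, 0.42, 0.09)
  tol <- 3 * sqrt(expected * (1 - expected) / 10000)
  expect_true(all(abs(as.numeric(counts) - expected) < tol))

  # divergence 1: every inside SNP is a fixed difference; arrangement
  # heterozygotes are heterozygous at all of them
  pop1 <- simulate_population(lay, n = 100, divergence = 1, seed = 5)
  ins <- pop1$site_freqs$inv == 1
  hets <- pop1$inv_truth[, 1] == 1L
  expect_true(all(pop1$genotypes$geno[ins, hets] == 1L))
  expect_true(all(abs(pop1$site_freqs$pd[ins] - pop1$site_freqs$pa[ins] - 1) < 1e-12))

  expect_error(simulate_population(lay, n = 1), "at least 2")
  expect_identical(simulate_population(lay, n = 20, seed = 3)$genotypes$geno,
                   simulate_population(lay, n = 20, seed = 3)$genotypes$geno)
})

test_that("gamma interference regularizes crossover counts below Poisson dispersion", {
  lay <- simulate_genome(c(LG1 = 1e7), c(LG1 = 200), markers_per_lg = 20,
                         seed = 2)
  n_off <- 400L
  counts_for <- function(mode) {
    cfg <- sim_config(n_families = 1L, offspring = n_off, error_rate = 0,
                      missing_rate = 0, interference = mode, nu = 5, seed = 6)
    fam <- simulate_family(lay, cfg, 1)
    tab <- table(factor(paste(fam$crossovers$offspring_id, fam$crossovers$parent),
                        levels = outer(fam$pedigree$id[-(1:2)],
                                       c("father", "mother"), paste)))
    as.numeric(tab)
  }
  pois <- counts_for("none")
  gam <- counts_for("gamma")
  # Poisson: index of dispersion ~ 1; gamma renewal (nu = 5): well below 1
  expect_lt(abs(stats::var(pois) / mean(pois) - 1), 0.25)
  expect_lt(stats::var(gam) / mean(gam), 0.7)
  expect_gt(mean(gam), 0.5 * mean(pois))  # comparable event numbers
})

test_that("resolved_crossovers gives marker-interval parity", {
  mk <- c(0, 10, 20, 30)
  expect_identical(resolved_crossovers(c(5), mk), 1L)
  expect_identical(resolved_crossovers(c(5, 6), mk), 0L)   # even parity: invisible
  expect_identical(resolved_crossovers(c(5, 6, 15), mk), 1L)
  expect_identical(resolved_crossovers(numeric(0), mk), 0L)
})
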
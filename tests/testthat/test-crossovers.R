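test_that("switch counting skips missing entries and matches a naive scan", {
  expect_equal(count_crossovers(c(0L, 0L, 1L, 1L))$count, 1L)
  expect_equal(count_crossovers(c(0L, 1L, 0L))$count, 2L)
  cc <- count_crossovers(c(0L, NA, 1L, 1L, NA, 1L), pos = c(1, 2, 3, 4, 5, 6))
  expect_equal(cc$count, 1L)
  expect_equal(unname(cc$intervals[1, ]), c(1, 3))  # flanking informative markers
  expect_equal(count_crossovers(integer(0))$count, 0L)
  expect_equal(count_crossovers(c(NA, NA))$count, 0L)
  set.seed(12)
  for (i in 1:50) {
    hap <- sample(c(0L, 1L, NA), 30, replace = TRUE)
    expect_equal(count_crossovers(hap)$count, naive_switches(hap))
  }
  # inserting missing entries between markers never changes the count
  hap <- c(0L, 0L, 1L, 0L, 1L, 1L)
  hap_na <- c(0L, NA, 0L, 1L, NA, NA, 0L, 1L, 1L, NA)
  expect_equal(count_crossovers(hap)$count, count_crossovers(hap_na)$count)
  # despiking collapses isolated single-marker islands (double switches)
  spiky <- c(0L, 0L, 1L, 0L, 0L, 1L, 1L)
  expect_equal(count_crossovers(spiky)$count, 3L)
  expect_equal(count_crossovers(spiky, despike = TRUE)$count, 1L)
  expect_equal(count_crossovers(c(0L, 1L, 0L), despike = TRUE)$count, 0L)
})

test_that("events assign to regions by midpoint with half-open semantics", {
  ev <- data.frame(offspring_id = c("o1", "o1", "o2", "o3"),
                   family_id = c("F1", "F1", "F1", "F1"),
                   parent = "father", lg = "LG1",
                   left = c(4.9e6, 1e6, 3.9e6, 6.1e6),
                   right = c(5.1e6, 1.2e6, 4.1e6, 6.3e6))
  ev$midpoint <- (ev$left + ev$right) / 2
  ev$weight <- 1 / 65
  class(ev) <- c("crossover_set", "data.frame")
  reg <- region_set("LG1", 4e6, 6e6, id = "R")
  tal <- assign_events(ev, reg)
  expect_equal(tal$n_events, 2)                      # 5.0 Mb and 4.0 Mb midpoints
  expect_equal(tal$weighted, 2 / 65, tolerance = 1e-12)
  # midpoint exactly at region start is inside (half-open)
  ev2 <- ev[3, ]; ev2$midpoint <- 4e6
  expect_equal(assign_events(ev2, reg)$n_events, 1)
  # ... and exactly at the end is outside
  ev3 <- ev[3, ]; ev3$midpoint <- 6e6
  expect_equal(nrow(assign_events(ev3, reg)), 0)
  # any-overlap rule picks up straddling events
  ev4 <- ev[4, ]; ev4$left <- 5.9e6; ev4$right <- 6.3e6; ev4$midpoint <- 6.1e6
  expect_equal(nrow(assign_events(ev4, reg)), 0)
  expect_equal(assign_events(ev4, reg, rule = "overlap")$n_events, 1)
  expect_error(assign_events(ev, region_set("LGX", 1, 2), known_lgs = "LG1"),
               "unknown LG")
})

test_that("on truth transmissions, counted events match marker-resolved truth", {
  inv <- region_set("LG1", 2e6, 5e6, derived_freq = 0.4, id = "i1")
  lay <- toy_layout(n_lg = 2, cm = 60, inv = inv, markers = 150, seed = 19)
  cfg <- sim_config(n_families = 1L, offspring = 60L, error_rate = 0,
                    missing_rate = 0, seed = 29)
  fam <- simulate_family(lay, cfg, 1)
  ev <- find_crossovers(fam$transmissions, c(F1 = 60))
  # per offspring x parent x LG, the count equals the parity-visible truth
  mk_by_lg <- split(fam$transmissions, fam$transmissions$parent)
  for (p in c("father", "mother")) {
    tr_p <- fam$transmissions[fam$transmissions$parent == p, ]
    for (lg in unique(tr_p$lg)) {
      mk <- sort(unique(tr_p$pos[tr_p$lg == lg]))
      for (off in unique(tr_p$offspring_id)) {
        truth <- fam$crossovers
        tpos <- truth$pos[truth$offspring_id == off & truth$parent == p &
                            truth$lg == lg]
        got <- sum(ev$offspring_id == off & ev$parent == p & ev$lg == lg)
        expect_identical(got, as.integer(resolved_crossovers(tpos, mk)))
      }
    }
  }
  # every event interval brackets at least one true crossover
  for (i in seq_len(nrow(ev))) {
    tpos <- fam$crossovers$pos[fam$crossovers$offspring_id == ev$offspring_id[i] &
                                 fam$crossovers$parent == ev$parent[i] &
                                 fam$crossovers$lg == ev$lg[i]]
    expect_true(any(tpos > ev$left[i] & tpos < ev$right[i]))
  }
})

test_that("rank-sum test is exact under ties and matches stats::wilcox.test", {
  # complete separation with within-group ties: exact p = 1 / C(20, 10)
  w <- wilcoxon_ranksum(rep(0, 10), 1:10, "less")
  expect_equal(w$method, "exact")
  expect_equal(w$p_value, 1 / choose(20, 10), tolerance = 1e-12)
  # identical groups: one-sided p about 0.5
  w2 <- wilcoxon_ranksum(rep(2, 6), rep(2, 6), "less")
  expect_gt(w2$p_value, 0.49)
  # tie-free small samples: agrees with R's exact Wilcoxon
  set.seed(33)
  for (i in 1:20) {
    x <- round(rnorm(sample(3:10, 1)), 4)
    y <- round(rnorm(sample(3:10, 1), mean = 0.5), 4)
    for (alt in c("less", "greater", "two.sided")) {
      ours <- wilcoxon_ranksum(x, y, alt)$p_value
      ref <- stats::wilcox.test(x, y, alternative = alt, exact = TRUE)$p.value
      expect_equal(ours, ref, tolerance = 1e-10)
    }
  }
  expect_error(wilcoxon_ranksum(numeric(0), 1:3), "empty")
})

test_that("the suppression test separates het and hom karyotypes", {
  counts <- data.frame(weighted = c(rep(0, 10), seq(0.05, 0.5, length.out = 10)),
                       karyotype = rep(c(1L, 0L), each = 10))
  res <- het_suppression_test(counts)
  expect_equal(res$p_value, 1 / choose(20, 10), tolerance = 1e-12)
  expect_error(het_suppression_test(data.frame(weighted = 1, karyotype = 1L)),
               "homokaryotype")
  expect_error(het_suppression_test(data.frame(weighted = 1, karyotype = 0L)),
               "heterokaryotype")
})
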
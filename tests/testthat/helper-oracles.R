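# Independent oracles used to cross-check the package's own implementations.
# Each deliberately takes a different computational route than the code it
# verifies.

# two-point LOD by grid-search likelihood maximization over r in [0, 0.5]
grid_lod <- function(tA, tB, grid = seq(0, 0.5, by = 1e-5)) {
  ok <- !is.na(tA) & !is.na(tB)
  n <- sum(ok)
  k <- sum(tA[ok] != tB[ok])
  k <- min(k, n - k)
  ll <- vapply(grid, function(r) {
    t1 <- if (k == 0) 0 else k * log10(r / 0.5)
    t2 <- if (k == n) 0 else (n - k) * log10((1 - r) / 0.5)
    t1 + t2
  }, numeric(1))
  list(r = grid[which.max(ll)], lod = max(ll))
}

# naive switch counting: explicit loop over the non-missing subsequence
naive_switches <- function(hap) {
  h <- hap[!is.na(hap)]
  cnt <- 0L
  if (length(h) >= 2)
    for (i in 2:length(h)) if (h[i] != h[i - 1]) cnt <- cnt + 1L
  cnt
}

# Weir-Cockerham Fst for one site via the two-level allele ANOVA
# (mean-squares route, distinct from the package's component formulas)
wc_fst_anova <- function(gA, gB) {
  gA <- gA[!is.na(gA)]; gB <- gB[!is.na(gB)]
  pops <- list(gA, gB)
  n_i <- lengths(pops)
  r <- 2L; n_tot <- sum(n_i)
  pij <- lapply(pops, function(g) g / 2)          # per-individual allele mean
  pbar_i <- vapply(pij, mean, numeric(1))
  ybar <- sum(n_i * pbar_i) / n_tot
  SSP <- sum(2 * n_i * (pbar_i - ybar)^2)
  SSI <- sum(vapply(seq_len(r), function(i) sum(2 * (pij[[i]] - pbar_i[i])^2),
                    numeric(1)))
  SSG <- sum(vapply(pops, function(g) sum(g == 1) * 0.5, numeric(1)))
  MSP <- SSP / (r - 1)
  MSI <- SSI / (n_tot - r)
  MSG <- SSG / n_tot
  nc <- (n_tot - sum(n_i^2) / n_tot) / (r - 1)
  a <- (MSP - MSI) / (2 * nc)
  b <- (MSI - MSG) / 2
  cc <- MSG
  a / (a + b + cc)
}

# Monte-Carlo oracle for the heterozygote-excess exact test: randomly pair
# the 2n alleles into n diploids and tabulate the heterozygote count
het_excess_mc <- function(n0, n1, n2, reps = 20000, seed = 1) {
  n <- n0 + n1 + n2
  alleles <- c(rep(1L, 2 * n0 + n1), rep(0L, 2 * n2 + n1))
  set.seed(seed)
  hits <- vapply(seq_len(reps), function(i) {
    a <- sample(alleles)
    sum(a[seq(1, 2 * n, 2)] != a[seq(2, 2 * n, 2)])
  }, integer(1))
  mean(hits >= n1)
}

# small synthetic genome shared by several tests
toy_layout <- function(n_lg = 2, lg_bp = 8e6, cm = 50, inv = NULL,
                       markers = 120, seed = 7, ...) {
  lgs <- paste0("LG", seq_len(n_lg))
  simulate_genome(stats::setNames(rep(lg_bp, n_lg), lgs),
                  stats::setNames(rep(cm, n_lg), lgs),
                  inversions = inv, markers_per_lg = markers, seed = seed, ...)
}
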
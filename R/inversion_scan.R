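#' @name inversion_scan
#' @title Population-panel inversion detection and genotyping
#'
#' @description
#' Inversions leave three fingerprints in a population panel: long-range
#' high LD, three-cluster PCA structure (the two arrangement homozygote
#' classes and the heterozygotes between them), and elevated windowed Fst
#' between arrangement homozygotes. This module applies genotype masking,
#' screens thinned SNPs for high-LD blocks, genotypes candidate regions by
#' 1-D k-means on PC1, computes Weir--Cockerham Fst in 100-kb windows
#' stepped by 20 kb, and calls the differentiation boundaries where Fst
#' rises above 0.15 over consecutive windows. Reported intervals describe
#' the region of sequence differentiation between arrangements, not the
#' exact inversion breakpoints.
NULL

#' Exact Hardy--Weinberg heterozygote-excess test
#'
#' One-sided exact test (Levene--Haldane conditional distribution of the
#' heterozygote count given the allele count) for an excess of
#' heterozygotes; used phred-scaled as an analog of the ExcessHet
#' annotation to flag collapsed paralogs and mapping artifacts.
#'
#' @param n0,n1,n2 genotype counts (hom ref, het, hom alt).
#' @return list with `p_value` (P(het >= observed)) and `phred`
#'   (-10 log10 p).
#' @export
excess_het_test <- function(n0, n1, n2) {
  n <- n0 + n1 + n2
  nA <- 2 * n0 + n1
  if (n == 0) return(list(p_value = 1, phred = 0))
  hets <- seq(nA %% 2, min(nA, 2 * n - nA), by = 2)
  logp <- lgamma(n + 1) - lgamma((nA - hets) / 2 + 1) - lgamma(hets + 1) -
    lgamma((2 * n - nA - hets) / 2 + 1) + hets * log(2) +
    lgamma(nA + 1) + lgamma(2 * n - nA + 1) - lgamma(2 * n + 1)
  pr <- exp(logp - max(logp)); pr <- pr / sum(pr)
  p <- sum(pr[hets >= n1])
  list(p_value = p, phred = -10 * log10(max(p, .Machine$double.xmin)))
}

#' Mask genotypes and drop low-confidence sites
#'
#' Genotype-level masks: DP below `dp_min` or GQ below `gq_min` set the
#' genotype to missing (skipped with a warning when the matrix lacks
#' DP/GQ). Site-level drops: non-biallelic sites, minor allele frequency
#' below `maf_min` (computed after genotype masking), sites whose mean
#' depth exceeds the panel mean + 1 SD of per-site mean depths, and sites
#' whose exact heterozygote-excess phred score exceeds
#' `excess_het_phred`.
#'
#' @param gm a [geno_matrix()].
#' @param dp_min,gq_min genotype-level thresholds (defaults 8 and 20).
#' @param maf_min site minor-allele-frequency floor (default 0.01).
#' @param excess_het_phred phred-scaled heterozygote-excess cutoff
#'   (default 54.69).
#' @param depth_cap_sd site mean-depth cap in SD units above the mean
#'   (default 1).
#' @return A masked, site-filtered `geno_matrix`; attribute `dropped`
#'   tabulates per-reason site counts.
#' @export
mask_genotypes <- function(gm, dp_min = 8, gq_min = 20, maf_min = 0.01,
                           excess_het_phred = 54.69, depth_cap_sd = 1) {
  stopifnot(inherits(gm, "geno_matrix"))
  geno <- gm$geno
  if (is.null(gm$dp) || is.null(gm$gq)) {
    warning("DP/GQ matrices absent: genotype-level masks skipped")
  } else {
    geno[gm$dp < dp_min | gm$gq < gq_min] <- NA_integer_
  }
  keep <- rep(TRUE, nrow(geno))
  dropped <- c(non_biallelic = 0L, maf = 0L, depth = 0L, excess_het = 0L)
  if (!is.null(gm$sites$biallelic)) {
    bad <- !gm$sites$biallelic
    dropped["non_biallelic"] <- sum(bad); keep[bad] <- FALSE
  }
  n_called <- rowSums(!is.na(geno))
  alt <- rowSums(geno, na.rm = TRUE) / (2 * pmax(1, n_called))
  maf <- pmin(alt, 1 - alt)
  bad <- keep & (n_called == 0 | maf < maf_min)
  dropped["maf"] <- sum(bad); keep[bad] <- FALSE
  if (!is.null(gm$dp)) {
    site_dp <- rowMeans(gm$dp, na.rm = TRUE)
    cap <- mean(site_dp) + depth_cap_sd * stats::sd(site_dp)
    bad <- keep & site_dp > cap
    dropped["depth"] <- sum(bad); keep[bad] <- FALSE
  }
  n1 <- rowSums(geno == 1L, na.rm = TRUE)
  n2 <- rowSums(geno == 2L, na.rm = TRUE)
  n0 <- n_called - n1 - n2
  idx <- which(keep)
  phred <- vapply(idx, function(i) excess_het_test(n0[i], n1[i], n2[i])$phred,
                  numeric(1))
  bad_eh <- idx[phred > excess_het_phred]
  dropped["excess_het"] <- length(bad_eh); keep[bad_eh] <- FALSE
  out <- geno_matrix(geno[keep, , drop = FALSE], gm$sites[keep, , drop = FALSE],
                     dp = if (!is.null(gm$dp)) gm$dp[keep, , drop = FALSE],
                     gq = if (!is.null(gm$gq)) gm$gq[keep, , drop = FALSE])
  attr(out, "dropped") <- dropped
  out
}

#' Genotype a candidate inversion region by PCA clustering
#'
#' Sites with more than `max_missing` missing genotypes are dropped and the
#' rest mean-imputed and centered; individuals are clustered by 1-D k-means
#' (k = 3) on PC1. Clusters ordered by center are assigned genotypes 0, 1, 2
#' (orientation is arbitrary: the low-PC1 homozygote class is labeled 0).
#' The call is flagged ambiguous unless all three clusters are occupied and
#' the middle (heterozygote) center lies within the middle third of the
#' interval between the homozygote centers — mirroring inversion-like vs
#' unresolved PCA patterns.
#'
#' In addition, the three clusters must be tight: the fraction of PC1
#' variance explained by the cluster assignment (k-means between-cluster
#' sum of squares over total) must reach `min_separation`. Genuine
#' arrangement clusters are near-discrete (fraction about 0.99) whereas
#' the optimal 3-way split of a continuous unimodal PC1 captures only
#' about 0.81, so the default 0.95 flags structureless regions as
#' ambiguous.
#'
#' @param gm a [geno_matrix()] restricted to the candidate region.
#' @param max_missing per-site missing fraction tolerated (default 0.2).
#' @param min_separation minimum between-cluster variance fraction of the
#'   3-cluster split (default 0.95).
#' @return list with `genotype` (0/1/2 per individual, NA when ambiguous),
#'   `ambiguous` (logical), `pc1`, `centers`, `var_explained` (PC1),
#'   `separation`.
#' @export
pca_genotype <- function(gm, max_missing = 0.2, min_separation = 0.95) {
  stopifnot(inherits(gm, "geno_matrix"))
  X <- t(gm$geno)  # individuals x sites
  if (nrow(X) < 3) stop("need at least 3 individuals")
  miss <- colMeans(is.na(X))
  X <- X[, miss <= max_missing, drop = FALSE]
  if (ncol(X) < 10) stop("need at least 10 usable SNPs in the region")
  mu <- colMeans(X, na.rm = TRUE)
  for (j in seq_len(ncol(X))) X[is.na(X[, j]), j] <- mu[j]
  X <- sweep(X, 2, colMeans(X))
  pc <- stats::prcomp(X, center = FALSE, scale. = FALSE, rank. = 2)
  pc1 <- pc$x[, 1]
  ve <- pc$sdev[1]^2 / sum(pc$sdev^2)
  amb <- function(msg, sep = NA_real_)
    list(genotype = rep(NA_integer_, nrow(X)), ambiguous = TRUE, reason = msg,
         pc1 = pc1, centers = NULL, var_explained = ve, separation = sep)
  if (length(unique(round(pc1, 10))) < 3) return(amb("fewer than 3 distinct PC1 values"))
  km <- stats::kmeans(pc1, centers = sort(stats::quantile(
    pc1, c(0.02, 0.5, 0.98), names = FALSE)), iter.max = 100)
  if (length(unique(km$cluster)) < 3) return(amb("fewer than 3 occupied clusters"))
  sep <- km$betweenss / km$totss
  ctr <- as.numeric(km$centers)
  o <- order(ctr)
  geno <- match(km$cluster, o) - 1L
  c_lo <- ctr[o[1]]; c_mid <- ctr[o[2]]; c_hi <- ctr[o[3]]
  if (abs(c_mid - (c_lo + c_hi) / 2) > (c_hi - c_lo) / 6)
    return(amb("heterozygote cluster not centered between homozygote clusters", sep))
  if (sep < min_separation)
    return(amb("clusters not separated beyond a continuous PC1 gradient", sep))
  list(genotype = stats::setNames(geno, rownames(X)), ambiguous = FALSE,
       reason = NULL, pc1 = pc1, centers = ctr[o], var_explained = ve,
       separation = sep)
}

# Weir & Cockerham (1984) per-site variance components a, b, c for 2 groups.
# Rows: sites. gA, gB: dosage matrices (sites x individuals) of each group.
.wc_components <- function(gA, gB) {
  nlist <- list(rowSums(!is.na(gA)), rowSums(!is.na(gB)))
  plist <- list(rowSums(gA, na.rm = TRUE) / (2 * pmax(1, nlist[[1]])),
                rowSums(gB, na.rm = TRUE) / (2 * pmax(1, nlist[[2]])))
  hlist <- list(rowSums(gA == 1L, na.rm = TRUE) / pmax(1, nlist[[1]]),
                rowSums(gB == 1L, na.rm = TRUE) / pmax(1, nlist[[2]]))
  r <- 2
  n1 <- nlist[[1]]; n2 <- nlist[[2]]
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * plist[[1]] + n2 * plist[[2]]) / (r * nbar)
  s2 <- (n1 * (plist[[1]] - pbar)^2 + n2 * (plist[[2]] - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * hlist[[1]] + n2 * hlist[[2]]) / (r * nbar)
  a <- (nbar / nc) * (s2 - (1 / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
    ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  usable <- n1 >= 1 & n2 >= 1 & nbar > 1 &
    !(plist[[1]] %in% c(0, 1) & plist[[2]] == plist[[1]])  # skip monomorphic
  data.frame(a = a, b = b, c = cc, usable = usable)
}

#' Windowed Weir--Cockerham Fst between arrangement homozygote groups
#'
#' Per window, the weighted estimator: the ratio of summed variance
#' components sum(a) / sum(a + b + c) over usable SNPs in the window
#' (SNPs monomorphic across both groups are skipped). Windows overlap:
#' default 100-kb windows stepped every 20 kb, per chromosome.
#'
#' @param gm a [geno_matrix()].
#' @param groupA,groupB character/integer indices of the two homozygote
#'   groups (each >= 2 individuals).
#' @param window_bp,step_bp window and step (defaults 100 kb / 20 kb).
#' @return An `fst_track` data.frame: `chrom`, `start`, `end`, `fst`
#'   (NA when no usable SNP), `n_snps`.
#' @export
windowed_fst <- function(gm, groupA, groupB, window_bp = 1e5, step_bp = 2e4) {
  stopifnot(inherits(gm, "geno_matrix"))
  gA <- gm$geno[, groupA, drop = FALSE]
  gB <- gm$geno[, groupB, drop = FALSE]
  if (ncol(gA) < 2 || ncol(gB) < 2) stop("both groups need >= 2 individuals")
  comp <- .wc_components(gA, gB)
  out <- lapply(unique(gm$sites$chrom), function(lg) {
    on <- gm$sites$chrom == lg
    pos <- gm$sites$pos[on]
    cp <- comp[on, , drop = FALSE]
    starts <- seq(0, max(pos), by = step_bp)
    res <- vapply(starts, function(s) {
      inw <- pos >= s & pos < s + window_bp & cp$usable
      if (!any(inw)) return(c(NA_real_, 0))
      c(sum(cp$a[inw]) / sum(cp$a[inw] + cp$b[inw] + cp$c[inw]), sum(inw))
    }, numeric(2))
    data.frame(chrom = lg, start = starts, end = starts + window_bp,
               fst = res[1, ], n_snps = as.integer(res[2, ]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  class(out) <- c("fst_track", "data.frame")
  out
}

#' Per-site Weir--Cockerham Fst
#'
#' Single-SNP convenience wrapper around the windowed estimator's variance
#' components: `a / (a + b + c)` per site.
#'
#' @param gm a [geno_matrix()].
#' @param groupA,groupB individual indices.
#' @return numeric vector per site (NA for unusable sites).
#' @export
site_fst <- function(gm, groupA, groupB) {
  comp <- .wc_components(gm$geno[, groupA, drop = FALSE],
                         gm$geno[, groupB, drop = FALSE])
  ifelse(comp$usable, comp$a / (comp$a + comp$b + comp$c), NA_real_)
}

#' Call differentiation boundaries from an Fst track
#'
#' A region starts at the first window of the earliest run of at least
#' `min_consecutive` windows with Fst above `threshold` and ends at the end
#' of the last window of that contiguous super-run; qualifying runs
#' separated by gaps shorter than `min_consecutive` windows are merged.
#' Windows with missing Fst (no usable SNP) carry no evidence in either
#' direction and are excluded before run detection — only an observed Fst
#' below the threshold counts as a return to background, so sparse marker
#' coverage inside a differentiated region cannot split the call.
#'
#' @param track an [windowed_fst()] result (one chromosome at a time, or
#'   the function is applied per chromosome).
#' @param threshold Fst cutoff (default 0.15).
#' @param min_consecutive minimum run length in windows (default 3).
#' @return data.frame of regions (`chrom`, `start`, `end`), zero rows when
#'   no run qualifies.
#' @export
call_boundaries <- function(track, threshold = 0.15, min_consecutive = 3L) {
  if (!nrow(track)) stop("empty Fst track")
  out <- lapply(unique(track$chrom), function(lg) {
    tr <- track[track$chrom == lg & !is.na(track$fst), , drop = FALSE]
    tr <- tr[order(tr$start), , drop = FALSE]
    if (!nrow(tr)) return(NULL)
    above <- tr$fst > threshold
    rl <- rle(above)
    ends <- cumsum(rl$lengths); starts <- ends - rl$lengths + 1
    qual <- which(rl$values & rl$lengths >= min_consecutive)
    if (!length(qual)) return(NULL)
    # merge qualifying runs across short sub-threshold gaps
    regions <- list(c(starts[qual[1]], ends[qual[1]]))
    for (q in qual[-1]) {
      gap <- starts[q] - regions[[length(regions)]][2] - 1
      if (gap < min_consecutive)
        regions[[length(regions)]][2] <- ends[q]
      else regions[[length(regions) + 1]] <- c(starts[q], ends[q])
    }
    do.call(rbind, lapply(regions, function(rg)
      data.frame(chrom = lg, start = tr$start[rg[1]], end = tr$end[rg[2]],
                 stringsAsFactors = FALSE)))
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(chrom = character(), start = numeric(), end = numeric())
  out
}

#' LD screen on thinned SNPs
#'
#' Keeps the first SNP passing the MAF filter in every `thin_bp` bin
#' (deterministic thinning), computes pairwise r-squared of genotype
#' dosages, and reports high-LD blocks: maximal runs of at least
#' `block_min` consecutive kept SNPs in which every `block_min`-SNP
#' sliding window has median pairwise r-squared above `r2_min`. Blocks are
#' candidate regions for [pca_genotype()].
#'
#' @param gm a [geno_matrix()].
#' @param thin_bp thinning bin (default 10 kb).
#' @param maf_min MAF floor applied before thinning (default 0.2).
#' @param r2_min,block_min block criteria (defaults 0.5 and 5).
#' @return list with `snps` (kept site table), `r2` (matrix, per
#'   chromosome block-diagonal sense: cross-chromosome pairs are NA),
#'   `blocks` (data.frame `chrom`, `start`, `end`, `n_snps`).
#' @export
ld_screen <- function(gm, thin_bp = 1e4, maf_min = 0.2, r2_min = 0.5,
                      block_min = 5L) {
  stopifnot(inherits(gm, "geno_matrix"))
  n_called <- rowSums(!is.na(gm$geno))
  alt <- rowSums(gm$geno, na.rm = TRUE) / (2 * pmax(1, n_called))
  maf <- pmin(alt, 1 - alt)
  pass <- maf > maf_min & n_called >= 2
  bin <- paste(gm$sites$chrom, floor(gm$sites$pos / thin_bp))
  cand <- which(pass)  # deterministic thinning: first passing SNP per bin
  keep <- cand[!duplicated(bin[cand])]
  if (length(keep) < 2)
    return(list(snps = gm$sites[keep, , drop = FALSE],
                r2 = matrix(numeric(0), 0, 0),
                blocks = data.frame(chrom = character(), start = numeric(),
                                    end = numeric(), n_snps = integer())))
  sites <- gm$sites[keep, , drop = FALSE]
  G <- t(gm$geno[keep, , drop = FALSE])
  r2 <- suppressWarnings(stats::cor(G, use = "pairwise.complete.obs"))^2
  blocks <- lapply(unique(sites$chrom), function(lg) {
    idx <- which(sites$chrom == lg)
    if (length(idx) < block_min) return(NULL)
    seed_ok <- vapply(seq_len(length(idx) - block_min + 1), function(i) {
      w <- idx[i:(i + block_min - 1)]
      sub <- r2[w, w]
      stats::median(sub[upper.tri(sub)], na.rm = TRUE) > r2_min
    }, logical(1))
    if (!any(seed_ok)) return(NULL)
    rl <- rle(seed_ok)
    ends <- cumsum(rl$lengths); starts <- ends - rl$lengths + 1
    hits <- which(rl$values)
    do.call(rbind, lapply(hits, function(h) {
      first <- idx[starts[h]]
      last <- idx[ends[h] + block_min - 1]
      data.frame(chrom = lg, start = sites$pos[first], end = sites$pos[last],
                 n_snps = last - first + 1L, stringsAsFactors = FALSE)
    }))
  })
  blocks <- do.call(rbind, blocks)
  if (is.null(blocks))
    blocks <- data.frame(chrom = character(), start = numeric(),
                         end = numeric(), n_snps = integer())
  # block end should cover the last SNP position (half-open interval)
  if (nrow(blocks)) blocks$end <- blocks$end + 1
  list(snps = sites, r2 = r2, blocks = blocks)
}
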
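#' @name region_stats
#' @title Collinear-vs-inversion rate permutation tests, feature densities,
#'   enrichment, and coverage-based sex linkage
#'
#' @description
#' Compares recombination rates between effectively collinear regions and
#' inversions (where suppression is expected in heterokaryotypes) with a
#' label permutation test; summarizes TE/gene interval tracks as windowed
#' densities; tests enrichment/depletion of features inside inversions by
#' randomly relocating inversion-sized segments; and classifies contigs as
#' autosomal or X-linked from sex-specific normalized coverage.
#'
#' All empirical p-values use the add-one rule
#' p = (1 + #(null at least as extreme)) / (n_perm + 1), so p is never 0,
#' and every permutation result records its seed.
NULL

#' Recombination rate per labeled region from a Marey map
#'
#' The genetic span of a region is the difference of cM values at its
#' endpoints, linearly interpolated between flanking markers; the rate is
#' that span divided by the physical span in Mb. Regions outside the mapped
#' extent are flagged missing.
#'
#' @param marey a [build_marey()] result for one LG.
#' @param regions a [region_set()] restricted to the same LG, with a
#'   `label` column (`"collinear"` / `"inversion"`) and optional `id`.
#' @return data.frame: `id`, `label`, `start`, `end`, `span_cM`, `span_Mb`,
#'   `rate` (NA when outside the mapped extent).
#' @export
region_rates <- function(marey, regions) {
  lo <- min(marey$bp); hi <- max(marey$bp)
  cm_at <- function(x) stats::approx(marey$bp, marey$cM, xout = x,
                                     ties = "ordered")$y
  out <- data.frame(
    id = if (!is.null(regions$id)) regions$id else seq_len(nrow(regions)),
    label = regions$label, start = regions$start, end = regions$end,
    span_cM = NA_real_, span_Mb = (regions$end - regions$start) / 1e6,
    rate = NA_real_, stringsAsFactors = FALSE)
  inside <- regions$start >= lo & regions$end <= hi
  if (any(inside)) {
    out$span_cM[inside] <- cm_at(regions$end[inside]) - cm_at(regions$start[inside])
    out$rate[inside] <- out$span_cM[inside] / out$span_Mb[inside]
  }
  out
}

#' Label permutation test: collinear vs inversion mean rates
#'
#' Statistic = mean(collinear rate) - mean(inversion rate). The null is
#' built by randomly reassigning the region labels (preserving group
#' sizes); the one-sided p-value is the add-one fraction of permutations
#' with a difference at least as large as observed.
#'
#' @param rates data.frame with `rate` and `label` in
#'   {"collinear", "inversion"} (e.g. stacked [region_rates()] output).
#' @param n_perm number of permutations (default 1000).
#' @param seed integer seed.
#' @return A `permutation_result` list: `observed`, `null`, `p_value`,
#'   `n_perm`, `seed`.
#' @export
label_permutation_test <- function(rates, n_perm = 1000L, seed = 1L) {
  rates <- rates[!is.na(rates$rate), , drop = FALSE]
  lab <- rates$label
  if (length(unique(lab)) < 2)
    stop("both labels (collinear, inversion) must be present")
  v <- rates$rate
  is_col <- lab == "collinear"
  obs <- mean(v[is_col]) - mean(v[!is_col])
  n <- length(v); ncol_ <- sum(is_col)
  with_seed_(seed, {
    null <- vapply(seq_len(n_perm), function(i) {
      idx <- sample.int(n, ncol_)
      mean(v[idx]) - mean(v[-idx])
    }, numeric(1))
    structure(list(observed = obs, null = null,
                   p_value = (1 + sum(null >= obs - 1e-12)) / (n_perm + 1),
                   n_perm = n_perm, seed = seed),
              class = "permutation_result")
  })
}

# total bp of the union of [start,end) intervals, via IRanges::reduce
.union_bp <- function(start, end) {
  if (!length(start)) return(0)
  ir <- IRanges::IRanges(start = as.integer(start) + 1L, end = as.integer(end))
  sum(IRanges::width(IRanges::reduce(ir)))
}

# merge a feature track once per LG into sorted non-overlapping intervals
.merge_features <- function(features) {
  out <- lapply(split(features, features$chrom), function(fe) {
    ir <- IRanges::reduce(IRanges::IRanges(start = as.integer(fe$start) + 1L,
                                           end = as.integer(fe$end)))
    cbind(start = IRanges::start(ir) - 1, end = IRanges::end(ir))
  })
  out
}

# feature bp inside regions, against a pre-merged track (fast inner loop)
.merged_bp_inside <- function(merged, chrom, start, end) {
  tot <- 0
  for (k in seq_along(chrom)) {
    fe <- merged[[chrom[k]]]
    if (is.null(fe)) next
    tot <- tot + sum(pmax(0, pmin(fe[, "end"], end[k]) - pmax(fe[, "start"], start[k])))
  }
  tot
}

#' Windowed feature density
#'
#' Tiles each LG with fixed windows from position 0 and reports, per
#' window, the fraction of bases covered by the union of the feature
#' intervals (overlaps merged).
#'
#' @param features a [region_set()] of feature intervals (e.g. TEs, genes).
#' @param lg_lengths_bp named vector of LG lengths.
#' @param window_bp window size (default 50 kb).
#' @return data.frame: `chrom`, `start`, `end`, `density` in [0, 1].
#' @export
window_density <- function(features, lg_lengths_bp, window_bp = 50000) {
  if (any(features$end < features$start)) stop("negative-width feature interval")
  out <- lapply(names(lg_lengths_bp), function(lg) {
    L <- lg_lengths_bp[[lg]]
    starts <- seq(0, max(0, L - 1), by = window_bp)
    ends <- pmin(starts + window_bp, L)
    fe <- features[features$chrom == lg, , drop = FALSE]
    dens <- vapply(seq_along(starts), function(i) {
      s <- pmax(fe$start, starts[i]); e <- pmin(fe$end, ends[i])
      keep <- s < e
      .union_bp(s[keep], e[keep]) / (ends[i] - starts[i])
    }, numeric(1))
    data.frame(chrom = lg, start = starts, end = ends, density = dens,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Permutation test of feature enrichment/depletion inside inversions
#'
#' Statistic = fraction of total feature bp lying inside the inversions.
#' The null relocates each inversion-sized segment to a uniformly chosen
#' start on a uniformly chosen LG that can hold it, redrawing on overlap
#' with already placed segments (rejection). Reported p is two-sided
#' (doubled smaller tail, add-one rule, capped at 1) with a direction
#' label.
#'
#' @param features a [region_set()] of feature intervals.
#' @param inversions a [region_set()] of inversion intervals.
#' @param lg_lengths_bp named vector of LG lengths.
#' @param n_perm permutations (default 1000).
#' @param seed integer seed.
#' @return A `permutation_result` with `observed`, `null`, `p_value`
#'   (two-sided), `direction` ("enriched"/"depleted"), `n_perm`, `seed`.
#' @export
enrichment_permutation <- function(features, inversions, lg_lengths_bp,
                                   n_perm = 1000L, seed = 1L) {
  widths <- inversions$end - inversions$start
  if (any(widths > max(lg_lengths_bp)))
    stop("an inversion is longer than every LG")
  merged <- .merge_features(features)
  total_fe <- sum(vapply(merged, function(m) sum(m[, "end"] - m[, "start"]),
                         numeric(1)))
  if (total_fe == 0) stop("feature track is empty")
  obs <- .merged_bp_inside(merged, inversions$chrom, inversions$start,
                           inversions$end) / total_fe
  lgs <- names(lg_lengths_bp)
  with_seed_(seed, {
    widths <- sort(widths, decreasing = TRUE)
    nw <- length(widths)
    null <- vapply(seq_len(n_perm), function(i) {
      pc <- character(nw); ps <- numeric(nw); pe <- numeric(nw)
      for (j in seq_len(nw)) {
        w <- widths[j]
        ok_lg <- lgs[lg_lengths_bp >= w]
        repeat {
          lg <- if (length(ok_lg) == 1) ok_lg else sample(ok_lg, 1)
          s <- stats::runif(1, 0, lg_lengths_bp[[lg]] - w)
          if (j == 1 || !any(pc[seq_len(j - 1)] == lg & ps[seq_len(j - 1)] < s + w &
                               pe[seq_len(j - 1)] > s)) break
        }
        pc[j] <- lg; ps[j] <- s; pe[j] <- s + w
      }
      .merged_bp_inside(merged, pc, ps, pe) / total_fe
    }, numeric(1))
    p_ge <- (1 + sum(null >= obs - 1e-12)) / (n_perm + 1)
    p_le <- (1 + sum(null <= obs + 1e-12)) / (n_perm + 1)
    structure(list(observed = obs, null = null,
                   p_value = min(1, 2 * min(p_ge, p_le)),
                   p_enriched = p_ge, p_depleted = p_le,
                   direction = if (obs >= stats::median(null)) "enriched" else "depleted",
                   n_perm = n_perm, seed = seed),
              class = "permutation_result")
  })
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("permutation test: observed %.4g, p = %.4g (%d permutations, seed %d)\n",
              x$observed, x$p_value, x$n_perm, x$seed))
  if (!is.null(x$direction)) cat("  direction:", x$direction, "\n")
  invisible(x)
}

#' Realized per-parent region rates: collinear vs inversion
#'
#' Partitions each LG into inversion intervals and the complementary
#' collinear segments, separately for each parent: an inversion counts as
#' "inversion" only where that parent is a heterokaryotype (karyotype 1);
#' inversions where the parent is homozygous behave collinearly and are
#' labeled accordingly. The realized rate of a region for a parent is
#' 100 x (crossover events with midpoint inside) / (offspring count x
#' span in Mb) — the empirical cM/Mb that parent's meioses exhibit there.
#'
#' @param events a [find_crossovers()] result.
#' @param layout a `genome_layout` (inversions + LG lengths).
#' @param karyotypes list per family of 2 x n_inversions matrices.
#' @param family_sizes named offspring counts per family.
#' @return data.frame with `family_id`, `parent`, `chrom`, `start`, `end`,
#'   `label`, `rate` — stackable input for [label_permutation_test()].
#' @export
parent_region_rates <- function(events, layout, karyotypes, family_sizes) {
  inv <- layout$inversions
  rows <- list()
  for (f in names(karyotypes)) for (p in c("father", "mother")) {
    n_off <- as.numeric(family_sizes[f])
    ev <- events[events$family_id == f & events$parent == p, , drop = FALSE]
    for (lg in names(layout$lg_lengths_bp)) {
      L <- layout$lg_lengths_bp[[lg]]
      iv <- inv[inv$chrom == lg, , drop = FALSE]
      het <- if (nrow(iv)) karyotypes[[f]][p, match(iv$id, inv$id)] == 1L else logical(0)
      segs <- list(); cur <- 0
      ivo <- order(iv$start)
      for (k in ivo) {
        if (iv$start[k] > cur)
          segs[[length(segs) + 1]] <- c(cur, iv$start[k], 0)
        segs[[length(segs) + 1]] <- c(iv$start[k], iv$end[k], as.integer(het[k]))
        cur <- iv$end[k]
      }
      if (cur < L) segs[[length(segs) + 1]] <- c(cur, L, 0)
      for (sg in segs) {
        n_ev <- sum(ev$lg == lg & .in_region(ev$midpoint, sg[1], sg[2]))
        rows[[length(rows) + 1]] <- data.frame(
          family_id = f, parent = p, chrom = lg, start = sg[1], end = sg[2],
          label = if (sg[3] == 1) "inversion" else "collinear",
          rate = 100 * n_ev / (n_off * (sg[2] - sg[1]) / 1e6),
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Classify contigs as autosomal / X-linked from normalized coverage
#'
#' Depths are assumed normalized per individual so the autosomal median
#' is 1.0. A contig is X-linked when the male median ratio falls in
#' `male_half` (around 0.5 — hemizygous males) while the female median is
#' near 1; autosomal when both sexes are near 1; otherwise ambiguous
#' (which includes the unresolved putative-Y pattern of X-like coverage
#' in both sexes).
#'
#' @param coverage matrix contigs x individuals of normalized depths.
#' @param sexes character vector ("M"/"F") per individual.
#' @param male_half,near_one acceptance bands (defaults [0.4, 0.6] and
#'   [0.85, 1.15]).
#' @return data.frame: `contig`, `male_median`, `female_median`, `class`
#'   in {"autosomal", "X-linked", "ambiguous"}.
#' @export
sex_linkage_scan <- function(coverage, sexes, male_half = c(0.4, 0.6),
                             near_one = c(0.85, 1.15)) {
  stopifnot(ncol(coverage) == length(sexes))
  if (!any(sexes == "M")) stop("no male individuals")
  if (!any(sexes == "F")) stop("no female individuals")
  mm <- apply(coverage[, sexes == "M", drop = FALSE], 1, stats::median)
  fm <- apply(coverage[, sexes == "F", drop = FALSE], 1, stats::median)
  in_band <- function(x, b) x >= b[1] & x <= b[2]
  cls <- ifelse(in_band(mm, male_half) & in_band(fm, near_one), "X-linked",
         ifelse(in_band(mm, near_one) & in_band(fm, near_one), "autosomal",
                "ambiguous"))
  data.frame(contig = if (!is.null(rownames(coverage))) rownames(coverage)
             else seq_len(nrow(coverage)),
             male_median = mm, female_median = fm, class = cls,
             stringsAsFactors = FALSE, row.names = NULL)
}
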
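#' @name crossovers
#' @title Crossover counting from phased transmissions and the
#'   heterokaryotype suppression test
#'
#' @description
#' Recombination events are counted as switches between consecutive
#' non-missing haplotype labels along each offspring x parent x LG
#' transmission vector. Events are localized to the interval between the
#' two flanking informative markers, assigned to genomic regions by the
#' interval midpoint, weighted by 1 / family offspring count, and compared
#' between inversion heterokaryotype and homokaryotype parents with a
#' one-sided Wilcoxon rank-sum test (exact permutation null for small
#' samples, normal approximation with tie correction otherwise).
NULL

#' Count haplotype switches in one transmission vector
#'
#' Missing entries are skipped; the count is the number of adjacent
#' non-missing pairs with different haplotype labels. Each event's interval
#' is the (bp-left, bp-right) pair of the flanking informative markers.
#'
#' @param hap integer vector of transmitted haplotypes {0, 1, NA}, ordered
#'   by position.
#' @param pos optional numeric positions aligned with `hap` (needed for
#'   event intervals).
#' @param despike drop isolated single-marker haplotype islands (a marker
#'   differing from both non-missing neighbours) before counting; such
#'   double switches are the signature of genotyping error rather than two
#'   tight crossovers. Off by default: raw switch counting is the
#'   reference behaviour.
#' @return list with `count` and `intervals` (2-column matrix left/right bp,
#'   NULL when `pos` is missing).
#' @export
count_crossovers <- function(hap, pos = NULL, despike = FALSE) {
  keep <- !is.na(hap)
  h <- hap[keep]
  if (despike && length(h) >= 3) {
    n <- length(h)
    spike <- c(FALSE, h[2:(n - 1)] != h[1:(n - 2)] & h[2:(n - 1)] != h[3:n],
               FALSE)
    keep[keep] <- !spike
    h <- h[!spike]
  }
  if (length(h) < 2) return(list(count = 0L, intervals = NULL))
  sw <- which(h[-1] != h[-length(h)])
  out <- list(count = length(sw), intervals = NULL)
  if (!is.null(pos) && length(sw)) {
    p <- pos[keep]
    out$intervals <- cbind(left = p[sw], right = p[sw + 1])
  }
  out
}

#' Enumerate crossover events from a transmission table
#'
#' @param transmissions data.frame with `offspring_id`, `family_id`,
#'   `parent`, `lg`, `pos`, `hap` (rows need not be pre-sorted; they are
#'   ordered by bp within each offspring x parent x LG).
#' @param family_sizes named vector: offspring count per family, used for
#'   the per-parent event weight 1 / family size.
#' @param despike passed to [count_crossovers()].
#' @return A `crossover_set` data.frame: one row per event with
#'   `offspring_id`, `family_id`, `parent`, `lg`, `left`, `right`,
#'   `midpoint`, `weight`.
#' @export
find_crossovers <- function(transmissions, family_sizes, despike = FALSE) {
  tr <- transmissions[order(transmissions$offspring_id, transmissions$parent,
                            transmissions$lg, transmissions$pos), ]
  key <- paste(tr$offspring_id, tr$parent, tr$lg, sep = "\r")
  groups <- split(seq_len(nrow(tr)), key)
  res <- lapply(groups, function(ix) {
    cc <- count_crossovers(tr$hap[ix], tr$pos[ix], despike = despike)
    if (cc$count == 0) return(NULL)
    data.frame(offspring_id = tr$offspring_id[ix[1]],
               family_id = tr$family_id[ix[1]],
               parent = tr$parent[ix[1]], lg = tr$lg[ix[1]],
               left = cc$intervals[, "left"], right = cc$intervals[, "right"],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(offspring_id = character(), family_id = character(),
                      parent = character(), lg = character(),
                      left = numeric(), right = numeric())
  rownames(out) <- NULL
  out$midpoint <- (out$left + out$right) / 2
  out$weight <- 1 / as.numeric(family_sizes[out$family_id])
  class(out) <- c("crossover_set", "data.frame")
  out
}

#' Assign crossover events to regions and tally weighted counts
#'
#' An event belongs to a region iff its interval midpoint lies inside the
#' (0-based half-open) region — the documented convention for events whose
#' interval straddles a region edge. Alternatively `rule = "overlap"`
#' counts any event whose interval intersects the region.
#'
#' @param events a [find_crossovers()] result.
#' @param regions a [region_set()] (non-overlapping within a comparison set;
#'   `chrom` must name known LGs when `known_lgs` is supplied).
#' @param rule `"midpoint"` (default) or `"overlap"`.
#' @param known_lgs optional character vector of valid LG names.
#' @return data.frame: one row per region x family x parent with `n_events`
#'   and `weighted` (= n_events / family offspring count); regions or
#'   parents with no events are absent (tally is sparse).
#' @export
assign_events <- function(events, regions, rule = c("midpoint", "overlap"),
                          known_lgs = NULL) {
  rule <- match.arg(rule)
  if (!is.null(known_lgs)) {
    bad <- setdiff(regions$chrom, known_lgs)
    if (length(bad)) stop("region on unknown LG: ", paste(bad, collapse = ", "))
  }
  rows <- lapply(seq_len(nrow(regions)), function(k) {
    on_lg <- events$lg == regions$chrom[k]
    hit <- if (rule == "midpoint")
      on_lg & .in_region(events$midpoint, regions$start[k], regions$end[k])
    else
      on_lg & events$right > regions$start[k] & events$left < regions$end[k]
    ev <- events[hit, , drop = FALSE]
    if (!nrow(ev)) return(NULL)
    agg <- stats::aggregate(cbind(n_events = rep(1, nrow(ev))),
                            by = list(family_id = ev$family_id, parent = ev$parent),
                            FUN = sum)
    agg$weighted <- agg$n_events * ev$weight[match(agg$family_id, ev$family_id)]
    cbind(region = if (!is.null(regions$id)) regions$id[k] else k,
          chrom = regions$chrom[k], agg)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(region = character(), chrom = character(),
                      family_id = character(), parent = character(),
                      n_events = numeric(), weighted = numeric())
  rownames(out) <- NULL
  out
}

#' Exact/approximate one-sided Wilcoxon rank-sum test
#'
#' One-sided test that values in `x` are stochastically smaller than in `y`.
#' For small samples (choose(nx+ny, nx) <= `exact_limit`) the permutation
#' null is enumerated exactly on midranks, which remains exact under ties;
#' otherwise the normal approximation with tie correction and continuity
#' correction is used.
#'
#' @param x,y numeric vectors (e.g. weighted crossover counts in
#'   heterokaryotype vs pooled homokaryotype parents).
#' @param alternative `"less"` (default: x < y), `"greater"`, `"two.sided"`.
#' @param exact_limit enumeration budget (number of assignments).
#' @return list with `statistic` (rank-sum of `x`, midranks), `p_value`,
#'   `method` (`"exact"` or `"normal"`).
#' @export
wilcoxon_ranksum <- function(x, y, alternative = c("less", "greater", "two.sided"),
                             exact_limit = 2e5) {
  alternative <- match.arg(alternative)
  if (!length(x)) stop("group 'x' is empty")
  if (!length(y)) stop("group 'y' is empty")
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  rk <- rank(pooled)
  W <- sum(rk[seq_len(nx)])
  n_comb <- choose(nx + ny, nx)
  if (n_comb <= exact_limit) {
    cmb <- utils::combn(nx + ny, nx)
    sums <- colSums(matrix(rk[cmb], nrow = nx))
    p <- switch(alternative,
      less = mean(sums <= W + 1e-9),
      greater = mean(sums >= W - 1e-9),
      two.sided = min(1, 2 * min(mean(sums <= W + 1e-9),
                                 mean(sums >= W - 1e-9))))
    list(statistic = W, p_value = p, method = "exact")
  } else {
    wt <- stats::wilcox.test(x, y, alternative = alternative,
                             exact = FALSE, correct = TRUE)
    list(statistic = W, p_value = wt$p.value, method = "normal")
  }
}

#' Heterokaryotype recombination-suppression test
#'
#' Pools per-inversion x parent weighted crossover counts into a
#' heterokaryotype group (parent karyotype 1 at that inversion) and a
#' homokaryotype group (karyotypes 0 and 2 treated as one group) and tests
#' whether heterokaryotypes show fewer events (one-sided Wilcoxon rank-sum
#' by default).
#'
#' @param counts data.frame with one row per inversion x parent:
#'   `weighted` (weighted event count) and `karyotype` (0/1/2).
#' @param alternative passed to [wilcoxon_ranksum()]; default `"less"`.
#' @return list with `statistic`, `p_value`, `method`, group sizes.
#' @export
het_suppression_test <- function(counts, alternative = "less") {
  het <- counts$weighted[counts$karyotype == 1]
  hom <- counts$weighted[counts$karyotype %in% c(0, 2)]
  if (!length(het)) stop("no heterokaryotype observations")
  if (!length(hom)) stop("no homokaryotype observations")
  res <- wilcoxon_ranksum(het, hom, alternative = alternative)
  res$n_het <- length(het); res$n_hom <- length(hom)
  res
}

#' Per-inversion x parent weighted crossover counts with karyotypes
#'
#' Convenience tally joining crossover events, inversion regions, and
#' per-family parental karyotypes into the input of
#' [het_suppression_test()]. Every parent x inversion combination appears,
#' including those with zero events.
#'
#' @param events a [find_crossovers()] result.
#' @param inversions a [region_set()] with an `id` column.
#' @param karyotypes list per family of 2 x n_inversions matrices (rows
#'   father/mother) as produced by [simulate_family()].
#' @param family_sizes named vector of offspring counts per family.
#' @return data.frame: `family_id`, `parent`, `inversion`, `karyotype`,
#'   `n_events`, `weighted`.
#' @export
inversion_event_table <- function(events, inversions, karyotypes, family_sizes) {
  fams <- names(karyotypes)
  rows <- list()
  for (f in fams) for (p in c("father", "mother")) for (k in seq_len(nrow(inversions))) {
    hit <- events$family_id == f & events$parent == p &
      events$lg == inversions$chrom[k] &
      .in_region(events$midpoint, inversions$start[k], inversions$end[k])
    n <- sum(hit)
    rows[[length(rows) + 1L]] <- data.frame(
      family_id = f, parent = p, inversion = inversions$id[k],
      karyotype = karyotypes[[f]][p, k],
      n_events = n, weighted = n / as.numeric(family_sizes[f]),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
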
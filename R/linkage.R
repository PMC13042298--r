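#' @name linkage
#' @title Desk-scale linkage-group assignment and marker ordering
#'
#' @description
#' A simplified analog of pairwise-LOD linkage mapping: two-point
#' recombination-fraction estimates and LOD scores from phase-known
#' transmission vectors, single-linkage grouping at a LOD threshold,
#' greedy nearest-neighbour seriation with 2-opt refinement, and
#' cumulative map distances through the Haldane or Kosambi mapping
#' function (Kosambi is the pipeline default, correcting for crossover
#' interference; Haldane matches an interference-free simulator).
NULL

#' Two-point recombination fraction and LOD score
#'
#' With k recombinant of n scored meioses, `r_hat = min(k/n, 0.5)` and
#' `lod = k log10(r/0.5) + (n-k) log10((1-r)/0.5)` evaluated at `r_hat`,
#' the phase (which transmission labeling counts as recombinant) chosen
#' to maximize the LOD; `0 log10(0)` is taken as 0. Meioses where either
#' vector is missing are dropped.
#'
#' @param tA,tB transmission vectors over the same meioses, entries in
#'   {0, 1, NA}.
#' @return list with `r_hat`, `lod`, `n_informative`, `k_recombinant`;
#'   `n_informative = 0` gives NA estimates (pair unusable).
#' @export
pairwise_lod <- function(tA, tB) {
  stopifnot(length(tA) == length(tB))
  ok <- !is.na(tA) & !is.na(tB)
  n <- sum(ok)
  if (n == 0)
    return(list(r_hat = NA_real_, lod = NA_real_, n_informative = 0L,
                k_recombinant = NA_integer_))
  k <- sum(tA[ok] != tB[ok])
  k <- min(k, n - k)  # phase maximizing the LOD
  r <- k / n
  lod <- if (r >= 0.5) 0 else .lod_at(k, n, r)
  list(r_hat = min(r, 0.5), lod = lod, n_informative = as.integer(n),
       k_recombinant = as.integer(k))
}

.lod_at <- function(k, n, r) {
  t1 <- if (k == 0) 0 else k * log10(r / 0.5)
  t2 <- if (k == n) 0 else (n - k) * log10((1 - r) / 0.5)
  t1 + t2
}

#' All-pairs LOD and recombination-fraction matrices
#'
#' Vectorized two-point estimation for a marker x meiosis transmission
#' matrix; equivalent to calling [pairwise_lod()] on every marker pair.
#'
#' @param M integer matrix (markers x meioses) of transmissions {0,1,NA}.
#' @return list of symmetric matrices `r` (phase-corrected recombination
#'   fraction), `lod`, and `n` (informative meioses); pairs with no
#'   jointly scored meiosis have NA `r`/`lod`.
#' @export
lod_matrix <- function(M) {
  M <- as.matrix(M)
  V <- !is.na(M)
  X <- M; X[!V] <- 0L
  storage.mode(X) <- "double"; storage.mode(V) <- "double"
  n <- tcrossprod(V)
  both1 <- tcrossprod(X)
  both0 <- tcrossprod(V - X)
  same <- both1 + both0
  k <- pmin(n - same, same)            # phase maximizing the LOD
  r <- ifelse(n > 0, k / n, NA_real_)
  lod <- matrix(0, nrow(M), nrow(M))
  pos <- n > 0
  t1 <- ifelse(k > 0, k * log10(ifelse(k > 0, r, 1) / 0.5), 0)
  t2 <- ifelse(n - k > 0, (n - k) * log10((1 - r) / 0.5), 0)
  lod[pos] <- (t1 + t2)[pos]
  lod[!pos] <- NA_real_
  lod[r >= 0.5 & pos] <- 0
  dimnames(r) <- dimnames(lod) <- dimnames(n) <- list(rownames(M), rownames(M))
  list(r = r, lod = lod, n = n)
}

#' Single-linkage grouping of markers at a LOD threshold
#'
#' Markers are joined whenever their pairwise LOD exceeds `lod_limit`;
#' linkage groups are the connected components of the resulting graph
#' (transitive closure), independent of marker input order. Unscored
#' pairs (NA) are treated as unlinked.
#'
#' @param lod symmetric LOD matrix from [lod_matrix()].
#' @param lod_limit threshold; default 19, the value at which the map
#'   this package emulates resolved its 16 linkage groups.
#' @return integer vector of group labels (1 = largest group), named by
#'   marker.
#' @export
assign_linkage_groups <- function(lod, lod_limit = 19) {
  m <- nrow(lod)
  parent <- seq_len(m)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  idx <- which(upper.tri(lod) & !is.na(lod) & lod > lod_limit, arr.ind = TRUE)
  for (e in seq_len(nrow(idx))) {
    a <- find(idx[e, 1]); b <- find(idx[e, 2])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  root <- vapply(seq_len(m), find, integer(1))
  sizes <- table(root)
  ord <- order(-as.integer(sizes), as.integer(names(sizes)))  # big first, ties by index
  lab <- stats::setNames(seq_along(ord), names(sizes)[ord])
  out <- lab[as.character(root)]
  names(out) <- rownames(lod)
  out
}

#' Genetic map distance and its inverse
#'
#' Kosambi: `d = 25 ln((1+2r)/(1-2r))` cM; Haldane: `d = -50 ln(1-2r)` cM.
#' Distances exceeding 1000 cM (r very close to 0.5) are capped with a
#' warning. The inverse functions are exact.
#'
#' @param r recombination fraction(s) in [0, 0.5).
#' @param d map distance(s) in cM, >= 0.
#' @param fn `"kosambi"` or `"haldane"`.
#' @return cM (resp. recombination fraction), vectorized.
#' @export
map_distance <- function(r, fn = c("kosambi", "haldane")) {
  fn <- match.arg(fn)
  if (any(r < 0 | r >= 0.5)) stop("r must be in [0, 0.5)")
  d <- if (fn == "kosambi") 25 * log((1 + 2 * r) / (1 - 2 * r))
       else -50 * log(1 - 2 * r)
  if (any(d > 1000)) {
    warning("map distance capped at 1000 cM")
    d <- pmin(d, 1000)
  }
  d
}

#' @rdname map_distance
#' @export
map_distance_inv <- function(d, fn = c("kosambi", "haldane")) {
  fn <- match.arg(fn)
  if (any(d < 0)) stop("d must be >= 0")
  if (fn == "kosambi") 0.5 * tanh(d / 50) else (1 - exp(-d / 50)) / 2
}

#' Order markers within a linkage group
#'
#' Greedy nearest-neighbour seriation on pairwise recombination fractions,
#' refined by 2-opt moves minimizing the sum of adjacent `r_hat`, then
#' cumulative cM positions from adjacent fractions through the selected
#' mapping function. Orientation is canonicalized: the end whose marker has
#' the lower physical position (or lexicographically smaller id when no
#' positions are given) comes first. 2-opt ties are broken toward the
#' earlier move for determinism.
#'
#' @param r symmetric recombination-fraction matrix for the group's markers
#'   (from [lod_matrix()], subset to the group).
#' @param mapping_function `"kosambi"` (default) or `"haldane"`.
#' @param physical_pos optional named vector of physical positions used for
#'   orientation.
#' @param max_sweeps 2-opt sweep limit.
#' @return A `linkage_group_map`: data.frame with `marker`, `rank`,
#'   `cum_cM`; attribute `mapping_function`.
#' @export
order_markers <- function(r, mapping_function = c("kosambi", "haldane"),
                          physical_pos = NULL, max_sweeps = 25L) {
  mapping_function <- match.arg(mapping_function)
  m <- nrow(r)
  if (m < 2) stop("group must contain at least 2 markers")
  ids <- rownames(r)
  if (is.null(ids)) ids <- as.character(seq_len(m))
  D <- r
  diag(D) <- Inf
  na <- is.na(D)
  if (any(na)) D[na] <- 0.5  # unscored pairs: treated as maximally distant
  if (m == 2) {
    ord <- 1:2
  } else {
    # greedy path: start from the marker with the largest nearest-neighbour
    # distance (a putative end), then extend to nearest unused marker
    start <- which.max(apply(D, 1, min))
    ord <- integer(m); used <- logical(m)
    ord[1] <- start; used[start] <- TRUE
    for (i in 2:m) {
      d <- D[ord[i - 1], ]; d[used] <- Inf
      nxt <- which.min(d)
      ord[i] <- nxt; used[nxt] <- TRUE
    }
    ord <- .two_opt(ord, D, max_sweeps)
  }
  # canonical orientation
  flip <- if (!is.null(physical_pos)) {
    p <- physical_pos[ids[ord]]
    isTRUE(p[length(p)] < p[1])
  } else ids[ord[m]] < ids[ord[1]]
  if (flip) ord <- rev(ord)
  adj <- pmin(D[cbind(ord[-m], ord[-1])], 0.499999)
  cum <- c(0, cumsum(suppressWarnings(map_distance(adj, mapping_function))))
  out <- data.frame(marker = ids[ord], rank = seq_len(m), cum_cM = cum,
                    stringsAsFactors = FALSE)
  attr(out, "mapping_function") <- mapping_function
  class(out) <- c("linkage_group_map", "data.frame")
  out
}

# path 2-opt: reverse ord[i..j] when it shortens the path; first-improvement
.two_opt <- function(ord, D, max_sweeps) {
  m <- length(ord)
  for (sweep in seq_len(max_sweeps)) {
    improved <- FALSE
    for (i in 1:(m - 1)) {
      for (j in (i + 1):m) {
        a <- if (i > 1) D[ord[i - 1], ord[i]] else 0
        b <- if (j < m) D[ord[j], ord[j + 1]] else 0
        a2 <- if (i > 1) D[ord[i - 1], ord[j]] else 0
        b2 <- if (j < m) D[ord[i], ord[j + 1]] else 0
        if (a2 + b2 < a + b - 1e-12) {
          ord[i:j] <- rev(ord[i:j])
          improved <- TRUE
        }
      }
    }
    if (!improved) break
  }
  ord
}
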
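#' @name marey
#' @title Marey maps, sliding-window recombination rates, map summaries
#'
#' @description
#' A Marey map plots cumulative genetic position (cM) against physical
#' position (bp); its local slope is the recombination rate in cM/Mb.
#' This module builds Marey maps from ordered linkage-group maps, estimates
#' windowed rates by ordinary least-squares regression with a window size
#' fixed per LG, flags candidate misassemblies as large genetic gaps
#' between physically adjacent markers, and computes per-LG and total
#' map summary statistics.
NULL

#' Build a Marey map from an ordered map and physical positions
#'
#' Points are sorted by physical position; markers sharing a position are
#' collapsed to their mean cM. Monotonicity violations (cM decreasing with
#' bp) are retained but counted in the `n_nonmonotone` attribute as a
#' diagnostic of ordering/anchoring disagreement.
#'
#' @param map a `linkage_group_map` (or data.frame with `marker`, `cum_cM`).
#' @param physical_pos named numeric vector: physical bp per marker.
#' @param lg_id label stored with the map.
#' @return A `marey_map`: data.frame with `bp`, `cM`, sorted by `bp`.
#' @export
build_marey <- function(map, physical_pos, lg_id = "LG") {
  pos <- physical_pos[map$marker]
  if (any(is.na(pos))) stop("missing physical position for some markers")
  df <- data.frame(bp = as.numeric(pos), cM = map$cum_cM)
  df <- df[order(df$bp), , drop = FALSE]
  if (anyDuplicated(df$bp)) {
    agg <- stats::aggregate(cM ~ bp, df, mean)
    df <- agg[order(agg$bp), c("bp", "cM")]
  }
  if (nrow(df) < 2) stop("need at least 2 distinct physical positions")
  rownames(df) <- NULL
  attr(df, "lg_id") <- lg_id
  attr(df, "n_nonmonotone") <- sum(diff(df$cM) < 0)
  class(df) <- c("marey_map", "data.frame")
  df
}

#' Sliding-window recombination rate from a Marey map
#'
#' Windows tile the mapped extent from the first mapped bp with a width
#' fixed per LG (default: span / 20). The rate in a window is the OLS
#' slope of cM on Mb over the points inside it, clamped below at 0 (the
#' raw slope is kept in `slope_raw`); windows with fewer than 2 points get
#' a missing rate. The final partial window is kept if it holds >= 2 points.
#'
#' @param marey a [build_marey()] result.
#' @param window_bp window width in bp; default `span / 20`.
#' @return A `rate_track` data.frame: `start`, `end`, `rate` (cM/Mb),
#'   `slope_raw`, `n_points`; attribute `window_bp`.
#' @export
sliding_rate <- function(marey, window_bp = NULL) {
  span <- diff(range(marey$bp))
  if (is.null(window_bp)) window_bp <- span / 20
  if (window_bp <= 0) stop("window_bp must be > 0")
  first <- min(marey$bp)
  starts <- seq(first, max(marey$bp), by = window_bp)
  if (length(starts) > 1 && starts[length(starts)] >= max(marey$bp))
    starts <- starts[-length(starts)]
  out <- lapply(starts, function(s) {
    e <- s + window_bp
    inw <- marey$bp >= s & marey$bp < e
    if (s == starts[length(starts)]) inw <- marey$bp >= s & marey$bp <= e
    n <- sum(inw)
    if (n < 2 || length(unique(marey$bp[inw])) < 2)
      return(data.frame(start = s, end = e, rate = NA_real_,
                        slope_raw = NA_real_, n_points = n))
    x <- marey$bp[inw] / 1e6
    y <- marey$cM[inw]
    slope <- stats::cov(x, y) / stats::var(x)
    data.frame(start = s, end = e, rate = max(0, slope), slope_raw = slope,
               n_points = n)
  })
  out <- do.call(rbind, out)
  attr(out, "window_bp") <- window_bp
  attr(out, "lg_id") <- attr(marey, "lg_id")
  class(out) <- c("rate_track", "data.frame")
  out
}

#' Flag candidate misassembly breakpoints
#'
#' Contigs mis-joined in an assembly show up on a Marey map as large jumps
#' in genetic distance between physically adjacent markers; such places are
#' candidates for cutting. Returns the midpoint of every adjacent-marker
#' interval whose absolute cM difference exceeds `gap_cM`.
#'
#' @param marey a [build_marey()] result.
#' @param gap_cM threshold on |delta cM| between adjacent markers (default 10).
#' @return numeric vector of candidate cut positions (bp midpoints).
#' @export
detect_breaks <- function(marey, gap_cM = 10) {
  d <- abs(diff(marey$cM))
  hit <- which(d > gap_cM)
  (marey$bp[hit] + marey$bp[hit + 1]) / 2
}

#' Map summary statistics in the style of a per-LG map table
#'
#' Computes per-LG recombination rates (cM/Mb), totals over the autosomal
#' subset and over all LGs, and Pearson r-squared of genetic length vs
#' physical size and of rate vs physical size across LGs.
#'
#' @param tab data.frame with one row per LG and columns `lg`, `length_cM`,
#'   `n_markers`, `length_Mb`; optionally `male_cM`, `male_markers`,
#'   `female_cM`, `female_markers`.
#' @param sex_lg character vector naming the sex-linked LG(s) excluded from
#'   the autosomal totals (default `"LG16"`).
#' @return A `map_summary` list: `per_lg` (with `rate_cM_Mb`), `totals`
#'   (autosomal and all-LG sums, overall mean rates), `r2` (named vector:
#'   `cM_vs_Mb`, `rate_vs_Mb`).
#' @export
map_summary <- function(tab, sex_lg = "LG16") {
  need <- c("lg", "length_cM", "n_markers", "length_Mb")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (any(is.na(tab$length_cM)) || any(is.na(tab$length_Mb)))
    stop("incomplete LG rows: ",
         paste(tab$lg[is.na(tab$length_cM) | is.na(tab$length_Mb)], collapse = ", "))
  per_lg <- tab
  per_lg$rate_cM_Mb <- per_lg$length_cM / per_lg$length_Mb
  auto <- !(per_lg$lg %in% sex_lg)
  tot <- function(idx, col) sum(per_lg[[col]][idx], na.rm = TRUE)
  totals <- list(
    autosomal_cM = tot(auto, "length_cM"),
    autosomal_markers = tot(auto, "n_markers"),
    autosomal_Mb = tot(auto, "length_Mb"),
    all_cM = tot(TRUE, "length_cM"),
    all_markers = tot(TRUE, "n_markers"),
    all_Mb = tot(TRUE, "length_Mb"))
  totals$autosomal_rate <- totals$autosomal_cM / totals$autosomal_Mb
  totals$all_rate <- totals$all_cM / totals$all_Mb
  for (sx in c("male", "female")) {
    cm <- paste0(sx, "_cM"); mk <- paste0(sx, "_markers")
    if (cm %in% names(per_lg)) {
      totals[[paste0(sx, "_autosomal_cM")]] <- tot(auto, cm)
      if (mk %in% names(per_lg))
        totals[[paste0(sx, "_autosomal_markers")]] <- tot(auto, mk)
    }
  }
  r2 <- c(cM_vs_Mb = stats::cor(per_lg$length_cM, per_lg$length_Mb)^2,
          rate_vs_Mb = stats::cor(per_lg$rate_cM_Mb, per_lg$length_Mb)^2)
  structure(list(per_lg = per_lg, totals = totals, r2 = r2),
            class = "map_summary")
}

#' @export
print.map_summary <- function(x, ...) {
  cat(sprintf("map_summary: %d LGs; autosomal %.0f cM / %d markers; all %.0f cM; mean rate %.2f cM/Mb\n",
              nrow(x$per_lg), x$totals$autosomal_cM, x$totals$autosomal_markers,
              x$totals$all_cM, x$totals$all_rate))
  cat(sprintf("  Pearson r2: cM~Mb %.2f, rate~Mb %.2f\n",
              x$r2[["cM_vs_Mb"]], x$r2[["rate_vs_Mb"]]))
  invisible(x)
}

#' Load the packaged per-LG map summary fixture
#'
#' The package ships the published per-LG table of the spruce bark beetle
#' linkage map (male, female, and sex-averaged lengths and marker counts
#' and physical sizes for 16 LGs) as a plain TSV.
#'
#' @return data.frame suitable for [map_summary()].
#' @export
read_map_table <- function() {
  path <- system.file("extdata", "ips_map_table.tsv", package = "recombinv",
                      mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
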
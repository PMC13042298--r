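#' Genotype matrix container
#'
#' A light container for biallelic-SNP genotypes: a sites x individuals
#' integer matrix of allele dosages (0, 1, 2, NA = missing), a site table
#' with chromosome/linkage-group, 0-based position, and alleles, and
#' optional per-genotype depth (DP) and quality (GQ) matrices.
#'
#' @param geno integer matrix, sites x individuals; entries in {0,1,2,NA}.
#' @param sites data.frame with columns `chrom`, `pos` (0-based), `id`,
#'   and optionally `ref`, `alt`, `biallelic` (logical).
#' @param dp,gq optional numeric matrices with the same dimensions as
#'   `geno` (per-genotype sequencing depth and phred genotype quality).
#' @return An object of class `geno_matrix`.
#' @export
geno_matrix <- function(geno, sites, dp = NULL, gq = NULL) {
  geno <- as.matrix(geno)
  stopifnot(is.data.frame(sites), nrow(sites) == nrow(geno),
            all(c("chrom", "pos") %in% names(sites)))
  if (is.null(sites$id)) sites$id <- paste0(sites$chrom, "_", sites$pos)
  bad <- geno[!is.na(geno)]
  if (length(bad) && !all(bad %in% 0:2))
    stop("genotypes must be dosages in {0, 1, 2} or NA")
  if (!is.null(dp)) stopifnot(all(dim(dp) == dim(geno)))
  if (!is.null(gq)) stopifnot(all(dim(gq) == dim(geno)))
  rownames(geno) <- sites$id
  structure(list(geno = geno, sites = sites, dp = dp, gq = gq),
            class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("geno_matrix: %d sites x %d individuals (%s DP/GQ)\n",
              nrow(x$geno), ncol(x$geno),
              if (is.null(x$dp)) "no" else "with"))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$geno)

#' Subset a genotype matrix by sites and/or individuals
#'
#' @param x a [geno_matrix()].
#' @param sites logical/integer index over sites.
#' @param individuals logical/integer/character index over individuals.
#' @return A `geno_matrix` restricted to the selection.
#' @export
subset_geno <- function(x, sites = NULL, individuals = NULL) {
  stopifnot(inherits(x, "geno_matrix"))
  if (is.null(sites)) sites <- seq_len(nrow(x$geno))
  if (is.null(individuals)) individuals <- seq_len(ncol(x$geno))
  geno_matrix(x$geno[sites, individuals, drop = FALSE],
              x$sites[sites, , drop = FALSE],
              dp = if (!is.null(x$dp)) x$dp[sites, individuals, drop = FALSE],
              gq = if (!is.null(x$gq)) x$gq[sites, individuals, drop = FALSE])
}

#' Labeled genomic intervals (0-based, half-open)
#'
#' @param chrom character vector of linkage group / chromosome names.
#' @param start,end integer vectors; 0-based half-open, `start < end`.
#' @param ... further per-interval columns (e.g. `id`, `derived_freq`).
#' @return A data.frame of class `region_set`.
#' @export
region_set <- function(chrom, start, end, ...) {
  start <- as.numeric(start); end <- as.numeric(end)
  if (any(start >= end)) stop("region_set: start must be < end (0-based half-open)")
  if (any(start < 0)) stop("region_set: negative start")
  df <- data.frame(chrom = as.character(chrom), start = start, end = end,
                   ..., stringsAsFactors = FALSE)
  class(df) <- c("region_set", "data.frame")
  df
}

# internal: half-open membership of point x in [start, end)
.in_region <- function(x, start, end) x >= start & x < end
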
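#' @name pedigree_markers
#' @title Informative-marker calling and map-entry filters
#'
#' @description
#' A marker informs on a parent's recombination only if that parent is
#' heterozygous while transmissions remain distinguishable. Markers are
#' classified per family as paternally, maternally, doubly, or not
#' informative, checked for Mendelian consistency, and filtered on minor
#' allele frequency, segregation distortion (explicit Pearson chi-square
#' against the Mendelian expectation of the cross type), missingness, and
#' the number of families in which they are informative.
NULL

# legal offspring dosages given two parental dosages
.legal_offspring <- function(gF, gM) {
  al <- function(g) switch(as.character(g), "0" = 0L, "1" = 0:1, "2" = 1L)
  unique(as.vector(outer(al(gF), al(gM), `+`)))
}

#' Classify markers by parental informativeness
#'
#' Per family: paternal if the father is heterozygous and the mother
#' homozygous, maternal if the reverse, both if both are heterozygous,
#' none otherwise (including any ungenotyped parent). A family's record is
#' demoted to none when any offspring genotype is impossible under
#' Mendelian transmission. MAF is computed across offspring of all
#' families (folded); missingness and the segregation chi-square p-value
#' are per family.
#'
#' @param gm a [geno_matrix()] containing parents and offspring.
#' @param pedigree data.frame with `family`, `id`, `father`, `mother`
#'   (parent rows carry NA father/mother).
#' @return data.frame, one row per marker x family: `marker_id`,
#'   `family_id`, `informativeness`, `maf`, `missing_fraction`,
#'   `segregation_p`.
#' @export
call_informative <- function(gm, pedigree) {
  stopifnot(inherits(gm, "geno_matrix"))
  unknown <- setdiff(pedigree$id, colnames(gm$geno))
  if (length(unknown))
    stop("pedigree individual(s) not in genotype matrix: ",
         paste(unknown, collapse = ", "))
  off <- pedigree[!is.na(pedigree$father), , drop = FALSE]
  fams <- unique(off$family)
  all_off_geno <- gm$geno[, off$id, drop = FALSE]
  alt <- rowSums(all_off_geno, na.rm = TRUE) /
    (2 * pmax(1, rowSums(!is.na(all_off_geno))))
  maf <- pmin(alt, 1 - alt)

  res <- lapply(fams, function(fam) {
    kids <- off[off$family == fam, , drop = FALSE]
    fa <- unique(kids$father); mo <- unique(kids$mother)
    if (length(fa) != 1 || length(mo) != 1)
      stop("family ", fam, " must have exactly one father and one mother")
    gF <- gm$geno[, fa]; gM <- gm$geno[, mo]
    K <- gm$geno[, kids$id, drop = FALSE]
    info <- rep("none", nrow(gm$geno))
    ok <- !is.na(gF) & !is.na(gM)
    info[ok & gF == 1L & gM %in% c(0L, 2L)] <- "paternal"
    info[ok & gM == 1L & gF %in% c(0L, 2L)] <- "maternal"
    info[ok & gF == 1L & gM == 1L] <- "both"
    segp <- rep(NA_real_, nrow(gm$geno))
    for (i in which(info != "none")) {
      legal <- .legal_offspring(gF[i], gM[i])
      obs_g <- K[i, ][!is.na(K[i, ])]
      if (length(obs_g) && !all(obs_g %in% legal)) { info[i] <- "none"; next }
      counts <- vapply(sort(legal), function(g) sum(obs_g == g), integer(1))
      expected <- if (info[i] == "both") c(1, 2, 1) / 4 else c(1, 1) / 2
      if (sum(counts) > 0) {
        stat <- sum((counts - sum(counts) * expected)^2 / (sum(counts) * expected))
        segp[i] <- stats::pchisq(stat, df = length(counts) - 1, lower.tail = FALSE)
      }
    }
    data.frame(marker_id = gm$sites$id, family_id = fam,
               informativeness = info, maf = maf,
               missing_fraction = rowMeans(is.na(K)),
               segregation_p = segp, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Filter informative markers for map construction
#'
#' A marker is retained iff (i) folded MAF >= `maf_min`, (ii) its
#' segregation p-value is >= `seg_alpha` in every family where it is
#' informative, (iii) its worst per-family missing fraction is
#' <= `missing_limit`, and (iv) it is informative (not "none") in at
#' least `family_informative_limit` families. The four conditions are a
#' conjunction, so filter order is irrelevant and the filter is
#' idempotent.
#'
#' @param markers output of [call_informative()].
#' @param maf_min,seg_alpha,missing_limit,family_informative_limit
#'   thresholds (defaults 0.1, 0.01, 0.1, 2).
#' @return the retained subset of `markers` (all family rows of retained
#'   markers); attribute `summary` gives the per-marker keep decision.
#' @export
filter_markers <- function(markers, maf_min = 0.1, seg_alpha = 0.01,
                           missing_limit = 0.1, family_informative_limit = 2L) {
  if (!nrow(markers)) {
    warning("empty marker table")
    return(markers)
  }
  sp <- split(markers, markers$marker_id)
  keep_tab <- do.call(rbind, lapply(sp, function(d) {
    inf <- d$informativeness != "none"
    data.frame(marker_id = d$marker_id[1],
               maf = d$maf[1],
               n_informative = sum(inf),
               min_seg_p = if (any(inf)) suppressWarnings(min(d$segregation_p[inf], na.rm = TRUE)) else NA_real_,
               max_missing = max(d$missing_fraction),
               stringsAsFactors = FALSE)
  }))
  keep_tab$keep <- keep_tab$maf >= maf_min &
    !is.na(keep_tab$min_seg_p) & keep_tab$min_seg_p >= seg_alpha &
    keep_tab$max_missing <= missing_limit &
    keep_tab$n_informative >= family_informative_limit
  out <- markers[markers$marker_id %in% keep_tab$marker_id[keep_tab$keep], ,
                 drop = FALSE]
  rownames(out) <- NULL
  attr(out, "summary") <- keep_tab
  out
}
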
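#' @name simdata
#' @title Synthetic pedigree and population data with known recombination truth
#'
#' @description
#' A seeded generator producing (i) a genome layout — linkage-group lengths,
#' a monotone physical-to-genetic ("Marey") truth function per LG, polymorphic
#' inversions with a derived-arrangement frequency, and TE/gene interval
#' tracks with configurable density multipliers inside inversions; (ii)
#' two-generation families with per-meiosis crossover positions, phased
#' parental transmissions and offspring genotypes; and (iii) population
#' panels in which SNP allele frequencies have diverged between the two
#' inversion arrangements. Every downstream stage of the package can be
#' exercised against the truth channel these functions emit.
#'
#' Crossovers are drawn per meiosis and LG as Poisson with mean equal to the
#' LG map length in Morgans (optionally a gamma-renewal process for positive
#' interference), placed uniformly on the genetic scale and mapped to bp
#' through the inverse truth function. In a parent heterozygous for an
#' inversion (heterokaryotype) every crossover falling inside that inversion
#' is removed and not relocated: suppression flattens the local map without
#' compensatory increase elsewhere.
NULL

# evaluate code with a temporary RNG seed, restoring the caller's stream
with_seed_ <- function(seed, code) {
  if (!is.null(seed)) {
    if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

#' Study-scale default genome dimensions
#'
#' Sixteen linkage groups (15 autosomes + X) with physical sizes (Mb) and
#' sex-averaged map lengths (cM) matching the spruce bark beetle map that
#' this package's fixtures describe.
#'
#' @return list with `lg_lengths_bp` and `map_lengths_cM` (named vectors).
#' @export
default_genome_dims <- function() {
  mb <- c(31.12, 26.55, 22.52, 14.41, 14.45, 12.14, 9.59, 8.70,
          9.86, 8.07, 11.01, 10.60, 7.77, 7.08, 9.53, 9.65)
  cm <- c(106.66, 101.02, 81.64, 52.38, 73.47, 51.36, 52.04, 53.06,
          45.24, 53.75, 81.1, 51.02, 67.38, 58.86, 48.65, 63.35)
  names(mb) <- names(cm) <- paste0("LG", seq_along(mb))
  list(lg_lengths_bp = mb * 1e6, map_lengths_cM = cm)
}

#' Simulate a genome layout
#'
#' @param lg_lengths_bp named numeric vector of LG physical lengths (bp).
#' @param map_lengths_cM named numeric vector of LG genetic lengths (cM);
#'   the truth Marey function of each LG is piecewise linear through
#'   `rate_nodes` if given, else uniform (linear 0 -> total cM).
#' @param inversions optional [region_set()] with columns `chrom`, `start`,
#'   `end`, `derived_freq` (frequency of the derived arrangement) and `id`.
#' @param markers_per_lg number of SNP marker positions drawn uniformly per
#'   LG (within the 1e2--1e4 per-LG density band typical of desk-scale maps).
#' @param te_density,gene_density genome-wide baseline fraction of bp covered
#'   by TE / gene features (defaults 0.23 and 0.30).
#' @param te_inversion_mult,gene_inversion_mult density multipliers applied
#'   inside inversions (default TE 0.5 = depleted, gene 1.5 = enriched).
#' @param feature_bp feature chunk size used when sampling interval tracks.
#' @param rate_nodes optional list per LG: data.frame(bp, cM) monotone nodes.
#' @param allow_overlap allow overlapping inversions on one LG.
#' @param seed integer seed; identical (arguments, seed) give identical layouts.
#' @return A `genome_layout`: list with `lg_lengths_bp`, `map_lengths_cM`,
#'   `marey_truth` (per-LG node data.frames), `inversions`, `markers`
#'   (data.frame lg/pos/id), `te_track`, `gene_track`.
#' @export
simulate_genome <- function(lg_lengths_bp = default_genome_dims()$lg_lengths_bp,
                            map_lengths_cM = default_genome_dims()$map_lengths_cM,
                            inversions = NULL,
                            markers_per_lg = 300,
                            te_density = 0.23, te_inversion_mult = 0.5,
                            gene_density = 0.30, gene_inversion_mult = 1.5,
                            feature_bp = 1000,
                            rate_nodes = NULL,
                            allow_overlap = FALSE,
                            seed = 1L) {
  stopifnot(length(lg_lengths_bp) >= 1, all(lg_lengths_bp > 0),
            length(map_lengths_cM) == length(lg_lengths_bp),
            all(map_lengths_cM > 0),
            te_density >= 0, gene_density >= 0)
  if (is.null(names(lg_lengths_bp)))
    names(lg_lengths_bp) <- paste0("LG", seq_along(lg_lengths_bp))
  names(map_lengths_cM) <- names(lg_lengths_bp)
  lgs <- names(lg_lengths_bp)

  if (!is.null(inversions)) {
    if (is.null(inversions$derived_freq))
      stop("inversions need a derived_freq column")
    if (is.null(inversions$id))
      inversions$id <- paste0("inv", seq_len(nrow(inversions)))
    bad_lg <- setdiff(inversions$chrom, lgs)
    if (length(bad_lg)) stop("inversion on unknown LG: ", paste(bad_lg, collapse = ", "))
    L <- lg_lengths_bp[inversions$chrom]
    if (any(inversions$start <= 0 | inversions$end >= L))
      stop("inversions must lie strictly inside their LG (not touching the ends)")
    if (!allow_overlap) {
      for (lg in unique(inversions$chrom)) {
        iv <- inversions[inversions$chrom == lg, , drop = FALSE]
        iv <- iv[order(iv$start), , drop = FALSE]
        if (nrow(iv) > 1 && any(iv$start[-1] < iv$end[-nrow(iv)]))
          stop("overlapping inversions on ", lg, " (set allow_overlap = TRUE to permit)")
      }
    }
  } else {
    inversions <- region_set(character(), numeric(0) + 1, numeric(0) + 2)[0, ]
    inversions$derived_freq <- numeric(0); inversions$id <- character(0)
  }

  marey_truth <- vector("list", length(lgs)); names(marey_truth) <- lgs
  for (lg in lgs) {
    nodes <- if (!is.null(rate_nodes) && !is.null(rate_nodes[[lg]])) {
      nd <- rate_nodes[[lg]]
      stopifnot(all(diff(nd$bp) > 0), all(diff(nd$cM) >= 0), nd$cM[1] == 0)
      # rescale so that total equals the configured map length
      nd$cM <- nd$cM * (map_lengths_cM[[lg]] / nd$cM[nrow(nd)])
      nd
    } else {
      data.frame(bp = c(0, lg_lengths_bp[[lg]]), cM = c(0, map_lengths_cM[[lg]]))
    }
    marey_truth[[lg]] <- nodes
  }

  with_seed_(seed, {
    markers <- do.call(rbind, lapply(lgs, function(lg) {
      pos <- sort(unique(floor(stats::runif(markers_per_lg, 0, lg_lengths_bp[[lg]]))))
      data.frame(lg = lg, pos = pos, id = paste0(lg, "_", pos),
                 stringsAsFactors = FALSE)
    }))
    sample_track <- function(base, mult) {
      out <- lapply(lgs, function(lg) {
        L <- lg_lengths_bp[[lg]]
        starts <- seq(0, L - feature_bp, by = feature_bp)
        mid <- starts + feature_bp / 2
        p <- rep(base, length(starts))
        iv <- inversions[inversions$chrom == lg, , drop = FALSE]
        for (k in seq_len(nrow(iv)))
          p[.in_region(mid, iv$start[k], iv$end[k])] <- base * mult
        keep <- stats::runif(length(starts)) < pmin(1, p)
        if (!any(keep)) return(NULL)
        data.frame(chrom = lg, start = starts[keep], end = starts[keep] + feature_bp,
                   stringsAsFactors = FALSE)
      })
      out <- do.call(rbind, out)
      if (is.null(out)) out <- data.frame(chrom = character(), start = numeric(), end = numeric())
      class(out) <- c("region_set", "data.frame")
      out
    }
    te_track <- sample_track(te_density, te_inversion_mult)
    gene_track <- sample_track(gene_density, gene_inversion_mult)
    structure(list(lg_lengths_bp = lg_lengths_bp,
                   map_lengths_cM = map_lengths_cM,
                   marey_truth = marey_truth,
                   inversions = inversions,
                   markers = markers,
                   te_track = te_track, gene_track = gene_track,
                   seed = seed),
              class = "genome_layout")
  })
}

#' Evaluate the truth Marey function (bp -> cM) or its inverse (cM -> bp)
#'
#' @param layout a `genome_layout`.
#' @param lg LG name.
#' @param bp,cM positions to convert.
#' @return numeric vector of cM (resp. bp).
#' @export
truth_cM <- function(layout, lg, bp) {
  nd <- layout$marey_truth[[lg]]
  stats::approx(nd$bp, nd$cM, xout = bp, rule = 2)$y
}

#' @rdname truth_cM
#' @export
truth_bp <- function(layout, lg, cM) {
  nd <- layout$marey_truth[[lg]]
  stats::approx(nd$cM, nd$bp, xout = cM, rule = 2, ties = "ordered")$y
}

#' Simulation configuration for the two-family pedigree design
#'
#' Defaults mirror the mapping design the package emulates: 2 families with
#' 65 and 82 offspring, Poisson crossovers (no interference), symmetric
#' uniform genotyping error and independent missingness.
#'
#' @param n_families number of families.
#' @param offspring integer vector of offspring counts per family.
#' @param parent_karyotypes optional list (one element per family) of
#'   2 x n_inversions integer matrices (rows `father`, `mother`; entries
#'   0/1/2 = copies of the derived arrangement). If `NULL`, karyotypes are
#'   drawn at Hardy--Weinberg proportions from each inversion's
#'   `derived_freq` when a family is simulated.
#' @param interference `"none"` (Poisson) or `"gamma"` (gamma-renewal
#'   inter-crossover distances, shape `nu`).
#' @param nu gamma-renewal shape (ignored for `"none"`).
#' @param error_rate per-genotype probability of a symmetric uniform
#'   mis-call (flip to one of the two other dosages).
#' @param missing_rate per-genotype probability of masking to NA.
#' @param informative_props probabilities that a marker is paternally,
#'   maternally, doubly, or not informative in a family.
#' @param suppression when `TRUE` (default), crossovers falling inside an
#'   inversion where the parent is a heterokaryotype are removed; set
#'   `FALSE` to generate a no-suppression null while keeping karyotype
#'   labels (for calibration of the suppression tests).
#' @param seed integer seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_families = 2L, offspring = c(65L, 82L),
                       parent_karyotypes = NULL,
                       interference = c("none", "gamma"), nu = 5,
                       error_rate = 0.001, missing_rate = 0.02,
                       informative_props = c(paternal = 0.4, maternal = 0.4,
                                             both = 0.15, none = 0.05),
                       suppression = TRUE,
                       seed = 1L) {
  interference <- match.arg(interference)
  stopifnot(error_rate >= 0, error_rate <= 1, missing_rate >= 0,
            missing_rate <= 1, length(offspring) == n_families,
            all(offspring > 0))
  if (!is.null(parent_karyotypes)) {
    stopifnot(is.list(parent_karyotypes), length(parent_karyotypes) == n_families)
    for (m in parent_karyotypes) stopifnot(all(m %in% 0:2))
  }
  structure(list(n_families = n_families, offspring = as.integer(offspring),
                 parent_karyotypes = parent_karyotypes,
                 interference = interference, nu = nu,
                 error_rate = error_rate, missing_rate = missing_rate,
                 suppression = isTRUE(suppression),
                 informative_props = informative_props, seed = as.integer(seed)),
            class = "sim_config")
}

# crossover positions (cM scale) for one meiosis
.draw_crossovers_cM <- function(map_cM, interference, nu) {
  M <- map_cM / 100
  if (interference == "none") {
    n <- stats::rpois(1, M)
    if (n == 0) return(numeric(0))
    sort(stats::runif(n, 0, map_cM))
  } else {
    # gamma-renewal from the origin; interarrivals mean 1 Morgan
    pos <- cumsum(stats::rgamma(max(4, ceiling(4 * M + 8)), shape = nu, rate = nu))
    while (length(pos) && pos[length(pos)] < M)
      pos <- c(pos, pos[length(pos)] +
                 cumsum(stats::rgamma(4, shape = nu, rate = nu)))
    100 * pos[pos < M]
  }
}

#' Simulate one family: meioses, transmissions, genotypes, truth channel
#'
#' For each offspring and parent, crossovers are drawn per LG (Poisson with
#' mean = map length in Morgans under `interference = "none"`), placed
#' uniformly on the genetic scale, converted to bp through the inverse truth
#' map, and — for inversions where the parent is a heterokaryotype — events
#' inside the inversion are deleted without relocation. Transmissions record,
#' at every marker informative for a parent, which parental haplotype (0/1)
#' the offspring received. Offspring genotypes are reconstructed from both
#' transmissions, then perturbed by the configured error and missingness.
#'
#' @param layout a `genome_layout` from [simulate_genome()].
#' @param config a [sim_config()].
#' @param family family index (1-based) into `config`.
#' @param family_id family label used in ids (default `"F<family>"`).
#' @param seed seed for this family; default derives from `config$seed`.
#' @return A `family_truth` list: `transmissions` (data.frame offspring_id,
#'   family_id, parent, lg, pos, marker_id, hap), `crossovers` (data.frame
#'   offspring_id, parent, lg, pos — true positions after suppression),
#'   `genotypes` ([geno_matrix()] of parents + offspring), `pedigree`,
#'   `karyotypes` (2 x n_inversions), `marker_info` (per-marker cross type).
#' @export
simulate_family <- function(layout, config, family = 1L,
                            family_id = paste0("F", family),
                            seed = config$seed + 1000L * family) {
  stopifnot(inherits(layout, "genome_layout"), inherits(config, "sim_config"))
  if (any(layout$map_lengths_cM <= 0)) stop("all LG map lengths must be > 0")
  n_off <- config$offspring[family]
  inv <- layout$inversions
  with_seed_(seed, {
    kary <- config$parent_karyotypes[[family]]
    if (is.null(kary)) {
      kary <- rbind(father = stats::rbinom(nrow(inv), 2, inv$derived_freq),
                    mother = stats::rbinom(nrow(inv), 2, inv$derived_freq))
    } else {
      kary <- as.matrix(kary)
      if (nrow(kary) != 2 || ncol(kary) != nrow(inv))
        stop("parent_karyotypes must be 2 x n_inversions for every inversion")
      rownames(kary) <- c("father", "mother")
    }
    if (nrow(inv)) colnames(kary) <- inv$id

    mk <- layout$markers
    type <- sample(names(config$informative_props), nrow(mk), replace = TRUE,
                   prob = config$informative_props)
    # parental genotypes by cross type (het parent phase: hap0 = ref, hap1 = alt)
    gF <- ifelse(type %in% c("paternal", "both"), 1L,
                 2L * stats::rbinom(nrow(mk), 1, 0.5))
    gM <- ifelse(type %in% c("maternal", "both"), 1L,
                 2L * stats::rbinom(nrow(mk), 1, 0.5))

    off_ids <- sprintf("%s_o%02d", family_id, seq_len(n_off))
    lgs <- names(layout$lg_lengths_bp)
    hapF <- matrix(NA_integer_, nrow(mk), n_off)   # transmitted haplotype
    hapM <- matrix(NA_integer_, nrow(mk), n_off)
    co <- list()
    for (parent in c("father", "mother")) {
      hap <- matrix(NA_integer_, nrow(mk), n_off)
      for (lg in lgs) {
        sel <- which(mk$lg == lg)
        mpos <- mk$pos[sel]
        supp <- if (nrow(inv) && config$suppression)
          inv[inv$chrom == lg & kary[parent, ] == 1L, , drop = FALSE]
        else inv[0, , drop = FALSE]
        for (i in seq_len(n_off)) {
          cm <- .draw_crossovers_cM(layout$map_lengths_cM[[lg]],
                                    config$interference, config$nu)
          bp <- truth_bp(layout, lg, cm)
          for (k in seq_len(nrow(supp)))
            bp <- bp[!.in_region(bp, supp$start[k], supp$end[k])]
          start <- stats::rbinom(1, 1, 0.5)
          hap[sel, i] <- (start + findInterval(mpos, sort(bp))) %% 2L
          if (length(bp))
            co[[length(co) + 1L]] <- data.frame(
              offspring_id = off_ids[i], parent = parent, lg = lg, pos = bp,
              stringsAsFactors = FALSE)
        }
      }
      if (parent == "father") hapF <- hap else hapM <- hap
    }
    crossovers <- if (length(co)) do.call(rbind, co) else
      data.frame(offspring_id = character(), parent = character(),
                 lg = character(), pos = numeric())

    # offspring dosage = transmitted paternal allele + maternal allele;
    # a homozygous parent contributes its fixed allele regardless of haplotype
    aF <- hapF; aF[gF != 1L, ] <- (gF[gF != 1L] / 2L)
    aM <- hapM; aM[gM != 1L, ] <- (gM[gM != 1L] / 2L)
    geno_off <- aF + aM
    geno <- cbind(matrix(c(gF, gM), ncol = 2,
                         dimnames = list(NULL, paste0(family_id, c("_father", "_mother")))),
                  geno_off)
    colnames(geno)[-(1:2)] <- off_ids

    # genotyping error: flip to a uniformly chosen different dosage
    if (config$error_rate > 0) {
      hit <- which(stats::runif(length(geno)) < config$error_rate)
      if (length(hit)) {
        shift <- sample(1:2, length(hit), replace = TRUE)
        geno[hit] <- (geno[hit] + shift) %% 3L
      }
    }
    if (config$missing_rate > 0)
      geno[stats::runif(length(geno)) < config$missing_rate] <- NA_integer_

    sites <- data.frame(chrom = mk$lg, pos = mk$pos, id = mk$id,
                        ref = "A", alt = "T", stringsAsFactors = FALSE)
    gm <- geno_matrix(geno, sites)

    # long-format truth transmissions at informative markers only
    tr <- list()
    for (parent in c("father", "mother")) {
      informative <- if (parent == "father") type %in% c("paternal", "both")
                     else type %in% c("maternal", "both")
      hap <- if (parent == "father") hapF else hapM
      idx <- which(informative)
      if (!length(idx)) next
      tr[[parent]] <- data.frame(
        offspring_id = rep(off_ids, each = length(idx)),
        family_id = family_id, parent = parent,
        lg = rep(mk$lg[idx], times = n_off),
        pos = rep(mk$pos[idx], times = n_off),
        marker_id = rep(mk$id[idx], times = n_off),
        hap = as.integer(hap[idx, ]),
        stringsAsFactors = FALSE)
    }
    transmissions <- do.call(rbind, tr)
    rownames(transmissions) <- NULL

    pedigree <- data.frame(
      family = family_id,
      id = c(paste0(family_id, c("_father", "_mother")), off_ids),
      father = c(NA, NA, rep(paste0(family_id, "_father"), n_off)),
      mother = c(NA, NA, rep(paste0(family_id, "_mother"), n_off)),
      sex = c("M", "F", rep(NA_character_, n_off)),
      stringsAsFactors = FALSE)

    structure(list(transmissions = transmissions, crossovers = crossovers,
                   genotypes = gm, pedigree = pedigree, karyotypes = kary,
                   marker_info = data.frame(mk, type = type),
                   family_id = family_id, seed = seed),
              class = "family_truth")
  })
}

#' Number of marker-resolved (parity-visible) crossovers
#'
#' At finite marker density an even number of crossovers between two
#' adjacent markers leaves no haplotype switch; transmissions can only
#' reveal crossovers up to parity within marker intervals. This helper
#' computes, from true crossover positions, the number of switches a
#' given marker grid can resolve — the exact expectation for switch
#' counting on error-free transmissions.
#'
#' @param positions numeric vector of true crossover bp on one LG (one
#'   meiosis, one parent).
#' @param marker_pos sorted marker positions on the same LG.
#' @return integer count of marker intervals with odd crossover parity.
#' @export
resolved_crossovers <- function(positions, marker_pos) {
  if (!length(positions) || length(marker_pos) < 2) return(0L)
  idx <- findInterval(positions, marker_pos)
  idx <- idx[idx >= 1 & idx < length(marker_pos)]  # outside the span: invisible
  if (!length(idx)) return(0L)
  sum(tabulate(idx, nbins = length(marker_pos) - 1) %% 2L == 1L)
}

#' Simulate a population panel with diverged inversion arrangements
#'
#' Individuals receive inversion genotypes at Hardy--Weinberg proportions
#' from each inversion's derived-arrangement frequency. Inside an inversion,
#' each SNP has arrangement-specific allele frequencies `m - d/2` (ancestral)
#' and `m + d/2` (derived) with the midpoint `m` drawn uniformly so both stay
#' in [0, 1]; a divergence of 1 therefore yields fixed differences at every
#' inside SNP. Outside inversions each SNP has a single panmictic frequency.
#'
#' @param layout a `genome_layout` (its `markers` define SNP positions and
#'   its `inversions` the arrangement polymorphisms).
#' @param n number of diploid individuals (default 240).
#' @param divergence per-inversion allele-frequency offset between
#'   arrangements, scalar or vector in [0, 1] (default 0.5).
#' @param depth_mean mean per-genotype sequencing depth (Poisson).
#' @param seed integer seed.
#' @return A `population_panel`: `genotypes` ([geno_matrix()] with DP/GQ),
#'   `inv_truth` (individuals x inversions matrix of 0/1/2 derived-arrangement
#'   copies), `divergence` (named per-inversion vector), `site_freqs`.
#' @export
simulate_population <- function(layout, n = 240L, divergence = 0.5,
                                depth_mean = 15, seed = 1L) {
  stopifnot(inherits(layout, "genome_layout"))
  if (n < 2) stop("need at least 2 individuals")
  inv <- layout$inversions
  if (nrow(inv) && (any(inv$derived_freq <= 0) || any(inv$derived_freq >= 1)))
    stop("inversion derived_freq must be in (0, 1)")
  divergence <- rep_len(divergence, nrow(inv))
  if (any(divergence < 0 | divergence > 1)) stop("divergence must be in [0, 1]")
  mk <- layout$markers
  ids <- sprintf("ind%03d", seq_len(n))
  with_seed_(seed, {
    inv_truth <- matrix(0L, n, nrow(inv),
                        dimnames = list(ids, if (nrow(inv)) inv$id))
    for (j in seq_len(nrow(inv)))
      inv_truth[, j] <- stats::rbinom(n, 2, inv$derived_freq[j])

    # per-SNP frequencies
    inv_of_snp <- rep(0L, nrow(mk))
    for (j in seq_len(nrow(inv))) {
      hit <- mk$lg == inv$chrom[j] & .in_region(mk$pos, inv$start[j], inv$end[j])
      inv_of_snp[hit] <- j
    }
    pa <- pd <- q <- numeric(nrow(mk))
    out <- inv_of_snp == 0L
    q[out] <- stats::runif(sum(out), 0.05, 0.95)
    for (j in seq_len(nrow(inv))) {
      s <- inv_of_snp == j
      d <- divergence[j]
      m <- stats::runif(sum(s), d / 2, 1 - d / 2)
      pa[s] <- m - d / 2
      pd[s] <- m + d / 2
    }

    geno <- matrix(NA_integer_, nrow(mk), n, dimnames = list(mk$id, ids))
    if (any(out))
      geno[out, ] <- stats::rbinom(sum(out) * n, 2, q[out])
    for (j in seq_len(nrow(inv))) {
      s <- which(inv_of_snp == j)
      if (!length(s)) next
      g <- inv_truth[, j]
      for (col in seq_len(n)) {
        geno[s, col] <- stats::rbinom(length(s), g[col], pd[s]) +
          stats::rbinom(length(s), 2L - g[col], pa[s])
      }
    }
    dp <- matrix(stats::rpois(length(geno), depth_mean), nrow(geno), ncol(geno))
    gq <- matrix(pmin(99L, stats::rpois(length(geno), 60)), nrow(geno), ncol(geno))
    sites <- data.frame(chrom = mk$lg, pos = mk$pos, id = mk$id,
                        ref = "A", alt = "T", stringsAsFactors = FALSE)
    structure(list(genotypes = geno_matrix(geno, sites, dp = dp, gq = gq),
                   inv_truth = inv_truth,
                   divergence = stats::setNames(divergence, if (nrow(inv)) inv$id),
                   site_freqs = data.frame(mk, inv = inv_of_snp, pa = pa,
                                           pd = pd, q = q),
                   seed = seed),
              class = "population_panel")
  })
}
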
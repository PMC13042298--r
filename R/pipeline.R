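#' @name pipeline
#' @title End-to-end pipeline over synthetic data
#'
#' @description
#' Composes the package's stages — simulate, informative-marker calling
#' and filtering, linkage grouping and ordering, Marey maps and rates,
#' crossover counting and the heterokaryotype suppression test, region
#' permutation tests, and the population inversion scan — into one
#' reproducible run. A single global seed is expanded into per-stage
#' child seeds (`seed + stage_index * 10007`) so stages can be re-run
#' individually; every written artifact carries the seed and a
#' configuration hash in its header.
NULL

#' Pipeline configuration
#'
#' Validates stage parameters against the known key set; unknown keys are
#' rejected before any stage runs.
#'
#' @param ... overrides of the defaults listed below.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    seed = 1L,
    n_lg = 4L, lg_length_bp = 8e6, map_length_cM = 60,
    markers_per_lg = 150L,
    n_inversions = 4L, inversion_span_bp = 1.5e6, derived_freq = 0.4,
    te_density = 0.23, te_inversion_mult = 0.5,
    offspring = c(65L, 82L),
    error_rate = 0.001, missing_rate = 0.02,
    lod_limit = 19, mapping_function = "kosambi",
    rate_window_frac = 20,
    n_perm = 1000L,
    panel_n = 120L, divergence = 0.5,
    fst_window_bp = 1e5, fst_step_bp = 2e4, fst_threshold = 0.15,
    min_consecutive = 3L,
    out_dir = NULL)
  ov <- list(...)
  unknown <- setdiff(names(ov), names(defaults))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  utils::modifyList(defaults, ov)
}

# stable short hash of a configuration (djb2 over its deparsed form)
config_hash <- function(config) {
  s <- paste(deparse(config[order(names(config))]), collapse = "")
  h <- 5381
  for (ch in utf8ToInt(s)) h <- (h * 33 + ch) %% 2^28
  sprintf("%07x", h)
}

#' Run the full pipeline on simulated data
#'
#' Builds a genome with regularly spaced inversions, simulates the
#' two-family pedigree and a population panel, and runs every downstream
#' stage. When `config$out_dir` is set, artifacts (transmissions TSV,
#' truth and called inversion BEDs, map/rate/summary TSVs, genotype VCF)
#' are written there, each with a seed + config-hash header.
#'
#' @param config a [pipeline_config()].
#' @return A report list with per-stage results; identical config and seed
#'   give identical reports.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  cfg <- config
  hash <- config_hash(cfg)
  child <- function(i) as.integer((cfg$seed + i * 10007L) %% .Machine$integer.max)
  hdr <- sprintf("# recombinv pipeline seed=%d config=%s", cfg$seed, hash)

  # --- simulate ---------------------------------------------------------
  lgs <- paste0("LG", seq_len(cfg$n_lg))
  lens <- stats::setNames(rep(cfg$lg_length_bp, cfg$n_lg), lgs)
  cms <- stats::setNames(rep(cfg$map_length_cM, cfg$n_lg), lgs)
  inv_lg <- lgs[1 + (seq_len(cfg$n_inversions) - 1) %% cfg$n_lg]
  inv_start <- cfg$lg_length_bp * (0.25 + 0.4 * (seq_len(cfg$n_inversions) - 1) %/% cfg$n_lg)
  inversions <- region_set(inv_lg, inv_start, inv_start + cfg$inversion_span_bp,
                           derived_freq = cfg$derived_freq,
                           id = paste0("inv", seq_len(cfg$n_inversions)))
  layout <- simulate_genome(lens, cms, inversions = inversions,
                            markers_per_lg = cfg$markers_per_lg,
                            te_density = cfg$te_density,
                            te_inversion_mult = cfg$te_inversion_mult,
                            seed = child(1))
  scfg <- sim_config(offspring = cfg$offspring, error_rate = cfg$error_rate,
                     missing_rate = cfg$missing_rate, seed = child(2))
  fams <- lapply(seq_along(cfg$offspring), function(f)
    simulate_family(layout, scfg, family = f))
  panel <- simulate_population(layout, n = cfg$panel_n,
                               divergence = cfg$divergence, seed = child(3))

  # --- markers ----------------------------------------------------------
  geno_all <- do.call(cbind, lapply(fams, function(f) f$genotypes$geno))
  gm <- geno_matrix(geno_all, fams[[1]]$genotypes$sites)
  pedigree <- do.call(rbind, lapply(fams, `[[`, "pedigree"))
  marker_calls <- call_informative(gm, pedigree)
  retained <- filter_markers(marker_calls)

  # --- linkage (father transmissions of family 1, desk-scale) -----------
  tr <- fams[[1]]$transmissions
  trf <- tr[tr$parent == "father", ]
  M <- transmission_matrix(trf)
  lm_ <- lod_matrix(M)
  groups <- assign_linkage_groups(lm_$lod, cfg$lod_limit)
  marker_pos <- stats::setNames(layout$markers$pos, layout$markers$id)
  maps <- lapply(sort(unique(groups[groups <= cfg$n_lg])), function(g) {
    ids <- names(groups)[groups == g]
    if (length(ids) < 2) return(NULL)
    order_markers(lm_$r[ids, ids], cfg$mapping_function,
                  physical_pos = marker_pos[ids])
  })
  maps <- Filter(Negate(is.null), maps)

  # --- marey ------------------------------------------------------------
  mareys <- lapply(maps, function(mp) build_marey(mp, marker_pos))
  rates <- lapply(mareys, sliding_rate)

  # --- crossovers + suppression -----------------------------------------
  trans_all <- do.call(rbind, lapply(fams, `[[`, "transmissions"))
  fam_sizes <- stats::setNames(cfg$offspring,
                               vapply(fams, `[[`, "", "family_id"))
  events <- find_crossovers(trans_all, fam_sizes)
  kary <- lapply(fams, `[[`, "karyotypes")
  names(kary) <- names(fam_sizes)
  ev_tab <- inversion_event_table(events, layout$inversions, kary, fam_sizes)
  suppression <- tryCatch(het_suppression_test(ev_tab),
                          error = function(e) list(p_value = NA_real_,
                                                   error = conditionMessage(e)))

  # --- region permutation tests -----------------------------------------
  rr <- parent_region_rates(events, layout, kary, fam_sizes)
  rate_perm <- label_permutation_test(rr, n_perm = cfg$n_perm, seed = child(4))
  te_perm <- enrichment_permutation(layout$te_track, layout$inversions,
                                    layout$lg_lengths_bp, n_perm = cfg$n_perm,
                                    seed = child(5))

  # --- inversion scan ---------------------------------------------------
  masked <- mask_genotypes(panel$genotypes)
  ld <- ld_screen(masked)
  calls <- list()
  for (b in seq_len(nrow(ld$blocks))) {
    blk <- ld$blocks[b, ]
    sel <- masked$sites$chrom == blk$chrom &
      masked$sites$pos >= blk$start & masked$sites$pos < blk$end
    if (sum(sel) < 10) next
    pg <- pca_genotype(subset_geno(masked, sites = sel))
    if (pg$ambiguous) next
    homA <- names(pg$genotype)[pg$genotype == 0]
    homB <- names(pg$genotype)[pg$genotype == 2]
    if (length(homA) < 2 || length(homB) < 2) next
    on_lg <- subset_geno(masked, sites = masked$sites$chrom == blk$chrom)
    fst <- windowed_fst(on_lg, homA, homB, cfg$fst_window_bp, cfg$fst_step_bp)
    bounds <- call_boundaries(fst, cfg$fst_threshold, cfg$min_consecutive)
    calls[[length(calls) + 1L]] <- list(block = blk, genotype = pg$genotype,
                                        fst = fst, boundaries = bounds)
  }

  report <- list(config = cfg, hash = hash, layout = layout,
                 families = fams, panel = panel,
                 marker_calls = marker_calls, retained = retained,
                 groups = groups, maps = maps, mareys = mareys, rates = rates,
                 events = events, event_table = ev_tab,
                 suppression = suppression,
                 region_rates = rr, rate_permutation = rate_perm,
                 te_enrichment = te_perm,
                 ld_blocks = ld$blocks, inversion_calls = calls)

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    p <- function(f) file.path(cfg$out_dir, f)
    write_transmissions(trans_all, p("transmissions.tsv"), hdr)
    write_regions(layout$inversions, p("inversions_truth.bed"), hdr)
    write_regions(events[, c("lg", "left", "right", "offspring_id")] |>
                    stats::setNames(c("chrom", "start", "end", "id")),
                  p("crossover_events.bed"), hdr)
    write_genotypes(panel$genotypes, p("panel.vcf"), sub("^#", "##", hdr))
    utils::write.table(ev_tab, p("inversion_event_counts.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    if (length(calls))
      write_regions(do.call(rbind, lapply(calls, function(cl) cl$boundaries)),
                    p("inversion_calls.bed"), hdr)
  }
  report
}

#' Reshape a long transmission table into a markers x meioses matrix
#'
#' @param tr transmission rows for a single parent (one meiosis per
#'   offspring): columns `marker_id`, `offspring_id`, `hap`.
#' @return integer matrix (markers x offspring) with NA for unscored cells,
#'   suitable for [lod_matrix()].
#' @export
transmission_matrix <- function(tr) {
  ids <- unique(tr$marker_id)
  offs <- unique(tr$offspring_id)
  M <- matrix(NA_integer_, length(ids), length(offs),
              dimnames = list(ids, offs))
  M[cbind(match(tr$marker_id, ids), match(tr$offspring_id, offs))] <- tr$hap
  M
}

# split each LG into labeled inversion / collinear regions
.partition_regions <- function(layout) {
  out <- lapply(names(layout$lg_lengths_bp), function(lg) {
    L <- layout$lg_lengths_bp[[lg]]
    iv <- layout$inversions[layout$inversions$chrom == lg, , drop = FALSE]
    iv <- iv[order(iv$start), , drop = FALSE]
    rows <- list(); cur <- 0
    for (k in seq_len(nrow(iv))) {
      if (iv$start[k] > cur)
        rows[[length(rows) + 1]] <- data.frame(chrom = lg, start = cur,
                                               end = iv$start[k], label = "collinear")
      rows[[length(rows) + 1]] <- data.frame(chrom = lg, start = iv$start[k],
                                             end = iv$end[k], label = "inversion")
      cur <- iv$end[k]
    }
    if (cur < L)
      rows[[length(rows) + 1]] <- data.frame(chrom = lg, start = cur, end = L,
                                             label = "collinear")
    do.call(rbind, rows)
  })
  out <- do.call(rbind, out)
  class(out) <- c("region_set", "data.frame")
  out
}
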
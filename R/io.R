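#' @name cli_io
#' @title Readers, writers, and pipeline plumbing
#'
#' @description
#' Minimal, lossless readers/writers for the formats the pipeline touches:
#' biallelic-SNP VCF 4.2 (GT:DP:GQ), BED interval tracks, and transmission
#' TSVs. Coordinates are 0-based half-open internally; VCF positions
#' (1-based) are converted at this boundary only. Every file written by the
#' pipeline carries a header comment with the seed and a configuration
#' hash.
NULL

#' Read biallelic SNP genotypes from a VCF
#'
#' Loads GT (as dosage 0/1/2), and DP/GQ when present, for biallelic SNP
#' records; indel and multiallelic records are skipped and counted in the
#' `skipped` attribute. VCF 1-based positions become internal 0-based.
#'
#' @param path VCF file (plain or bgzipped).
#' @return A [geno_matrix()] with attribute `skipped`.
#' @export
read_genotypes <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  snp <- nchar(fix$REF) == 1 & !grepl(",", fix$ALT) &
    nchar(fix$ALT) == 1 & fix$ALT %in% c("A", "C", "G", "T")
  skipped <- sum(!snp)
  gt <- vcfR::extract.gt(v, element = "GT")[snp, , drop = FALSE]
  dosage <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  clean <- gsub("\\|", "/", gt)
  dosage[clean == "0/0"] <- 0L
  dosage[clean %in% c("0/1", "1/0")] <- 1L
  dosage[clean == "1/1"] <- 2L
  has <- function(el) any(grepl(el, v@gt[, "FORMAT"]))
  num_mat <- function(el) {
    raw <- vcfR::extract.gt(v, el)[snp, , drop = FALSE]
    matrix(suppressWarnings(as.numeric(raw)), nrow(raw), ncol(raw),
           dimnames = dimnames(raw))
  }
  dp <- if (has("DP")) num_mat("DP")
  gq <- if (has("GQ")) num_mat("GQ")
  sites <- data.frame(chrom = fix$CHROM[snp],
                      pos = as.numeric(fix$POS[snp]) - 1,
                      id = ifelse(is.na(fix$ID[snp]) | fix$ID[snp] == ".",
                                  paste0(fix$CHROM[snp], "_", as.numeric(fix$POS[snp]) - 1),
                                  fix$ID[snp]),
                      ref = fix$REF[snp], alt = fix$ALT[snp],
                      stringsAsFactors = FALSE)
  out <- geno_matrix(dosage, sites, dp = dp, gq = gq)
  attr(out, "skipped") <- skipped
  out
}

#' Write a genotype matrix as minimal VCF 4.2
#'
#' @param gm a [geno_matrix()].
#' @param path output path (plain text).
#' @param header_extra optional character vector of extra `##` header lines
#'   (e.g. seed and config hash).
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(gm, path, header_extra = NULL) {
  stopifnot(inherits(gm, "geno_matrix"))
  samples <- colnames(gm$geno)
  with_fmt <- !is.null(gm$dp) && !is.null(gm$gq)
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           if (with_fmt) c(
             "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
             "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">"),
           header_extra,
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  gt_str <- matrix("./.", nrow(gm$geno), ncol(gm$geno))
  gt_str[gm$geno == 0L] <- "0/0"
  gt_str[gm$geno == 1L] <- "0/1"
  gt_str[gm$geno == 2L] <- "1/1"
  if (with_fmt) {
    gt_str <- matrix(paste(gt_str, as.integer(gm$dp), as.integer(gm$gq),
                           sep = ":"),
                     nrow(gm$geno), ncol(gm$geno))
    fmt <- "GT:DP:GQ"
  } else fmt <- "GT"
  body <- apply(cbind(gm$sites$chrom, format(gm$sites$pos + 1, scientific = FALSE, trim = TRUE),
                      gm$sites$id,
                      if (is.null(gm$sites$ref)) "A" else gm$sites$ref,
                      if (is.null(gm$sites$alt)) "T" else gm$sites$alt,
                      ".", "PASS", ".", fmt, gt_str),
                1, paste, collapse = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a BED interval file (0-based half-open)
#'
#' @param path BED file with >= 3 columns; column 4, when present, becomes
#'   `id`.
#' @param lg_lengths_bp optional named vector; intervals are validated
#'   against these bounds.
#' @return A [region_set()].
#' @export
read_regions <- function(path, lg_lengths_bp = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track")]
  if (!length(lines))
    return(region_set(character(), numeric(0) + 1, numeric(0) + 2)[0, ])
  parts <- strsplit(lines, "\t")
  nc <- lengths(parts)
  if (any(nc < 3)) stop("BED line ", which(nc < 3)[1], ": fewer than 3 columns")
  chrom <- vapply(parts, `[`, "", 1)
  start <- as.numeric(vapply(parts, `[`, "", 2))
  end <- as.numeric(vapply(parts, `[`, "", 3))
  bad <- which(is.na(start) | is.na(end) | start >= end)
  if (length(bad)) stop("BED line ", bad[1], ": start must be < end")
  if (!is.null(lg_lengths_bp)) {
    over <- which(end > lg_lengths_bp[chrom] | is.na(lg_lengths_bp[chrom]))
    if (length(over))
      stop("BED line ", over[1], ": interval beyond LG length")
  }
  rs <- region_set(chrom, start, end)
  if (all(nc >= 4)) rs$id <- vapply(parts, `[`, "", 4)
  rs
}

#' Write intervals as BED
#'
#' @param regions a [region_set()] (or data.frame with chrom/start/end and
#'   optional further columns, written as BED columns 4+).
#' @param path output path.
#' @param header_extra optional `#`-prefixed comment lines.
#' @return `path`, invisibly.
#' @export
write_regions <- function(regions, path, header_extra = NULL) {
  extra <- setdiff(names(regions), c("chrom", "start", "end"))
  df <- data.frame(regions$chrom,
                   format(regions$start, scientific = FALSE, trim = TRUE),
                   format(regions$end, scientific = FALSE, trim = TRUE))
  for (cn in extra) df[[cn]] <- regions[[cn]]
  lines <- apply(df, 1, paste, collapse = "\t")
  writeLines(c(header_extra, lines), path)
  invisible(path)
}

#' Read / write a transmission table TSV
#'
#' Columns: `offspring_id`, `family_id`, `parent`, `lg`, `pos`,
#'   `marker_id`, `hap` (0/1/NA).
#'
#' @param path TSV path.
#' @return data.frame (read) / `path` invisibly (write).
#' @export
read_transmissions <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
}

#' @rdname read_transmissions
#' @param transmissions the table to write.
#' @param header_extra optional `#` comment lines.
#' @export
write_transmissions <- function(transmissions, path, header_extra = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_extra)) writeLines(header_extra, con)
  utils::write.table(transmissions, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
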
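#' Construct a genotype object
#'
#' Bundles a dosage matrix with its marker map. Dosages count copies of the
#' first-listed allele of each marker and take values 0/1/2 with `NA` for a
#' missing call.
#'
#' @param dosages Numeric matrix, individuals x markers, with row names set to
#'   individual ids and column names to marker ids.
#' @param map Data frame with one row per marker: columns `marker`, `chrom`,
#'   `pos` (bp) and optionally `a1`, `a2`, aligned with the matrix columns.
#' @return Object of class `"geno"`: a list with elements `dosages` and `map`
#'   (tibble).
#' @export
genotypes <- function(dosages, map) {
  stopifnot(is.matrix(dosages))
  map <- tibble::as_tibble(map)
  if (nrow(map) != ncol(dosages)) {
    stop("marker map rows (", nrow(map), ") do not match genotype columns (",
         ncol(dosages), ")", call. = FALSE)
  }
  if (!all(c("marker", "chrom", "pos") %in% names(map))) {
    stop("map must have columns marker, chrom, pos", call. = FALSE)
  }
  if (is.null(rownames(dosages))) {
    rownames(dosages) <- paste0("id", seq_len(nrow(dosages)))
  }
  colnames(dosages) <- map$marker
  ok <- is.na(dosages) | dosages %in% 0:2
  if (!all(ok)) stop("dosages must be 0, 1, 2 or NA", call. = FALSE)
  structure(list(dosages = dosages, map = map), class = "geno")
}

#' @export
print.geno <- function(x, ...) {
  cat("<geno> ", nrow(x$dosages), " individuals x ", ncol(x$dosages),
      " markers on ", length(unique(x$map$chrom)), " chromosome(s)\n",
      sep = "")
  invisible(x)
}

#' @export
dim.geno <- function(x) dim(x$dosages)

.empty_report <- function() {
  tibble::tibble(stage = character(0), axis = character(0),
                 removed = integer(0), n_individuals = integer(0),
                 n_markers = integer(0))
}

.report <- function(geno) {
  rep <- attr(geno, "qc_report")
  if (is.null(rep)) .empty_report() else rep
}

.log_stage <- function(geno, stage, axis, removed) {
  rep <- dplyr::bind_rows(.report(geno), tibble::tibble(
    stage = stage, axis = axis, removed = as.integer(removed),
    n_individuals = nrow(geno$dosages), n_markers = ncol(geno$dosages)
  ))
  attr(geno, "qc_report") <- rep
  geno
}

#' QC removal report of a filtered genotype object
#'
#' @param geno A `"geno"` object that has passed through one or more QC
#'   filters.
#' @return Tibble with one row per filter stage: `stage`, `axis`
#'   (markers/individuals), `removed`, and the dimensions remaining after the
#'   stage.
#' @export
qc_report <- function(geno) .report(geno)

.subset_geno <- function(geno, rows = NULL, cols = NULL) {
  rep <- attr(geno, "qc_report")
  if (!is.null(cols)) {
    geno$dosages <- geno$dosages[, cols, drop = FALSE]
    geno$map <- geno$map[cols, , drop = FALSE]
  }
  if (!is.null(rows)) geno$dosages <- geno$dosages[rows, , drop = FALSE]
  attr(geno, "qc_report") <- rep
  geno
}

#' Remove markers and individuals with low call rate
#'
#' Markers are filtered first, then individual call rates are recomputed on
#' the retained markers. A call rate exactly at the threshold is retained
#' ("below" is strict).
#'
#' @param geno A `"geno"` object.
#' @param threshold Minimum fraction of non-missing calls (default 0.90).
#' @return Filtered `"geno"` with an updated QC report.
#' @export
filter_call_rate <- function(geno, threshold = 0.90) {
  stopifnot(threshold > 0, threshold <= 1)
  cr_m <- colMeans(!is.na(geno$dosages))
  keep_m <- cr_m >= threshold
  geno2 <- .subset_geno(geno, cols = which(keep_m))
  geno2 <- .log_stage(geno2, "call_rate", "markers", sum(!keep_m))
  cr_i <- rowMeans(!is.na(geno2$dosages))
  keep_i <- cr_i >= threshold
  if (!any(keep_i)) stop("call-rate filter removed every individual",
                         call. = FALSE)
  geno2 <- .subset_geno(geno2, rows = which(keep_i))
  .log_stage(geno2, "call_rate", "individuals", sum(!keep_i))
}

.allele_freq <- function(dosages) {
  colMeans(dosages, na.rm = TRUE) / 2
}

#' Remove markers with low minor allele frequency
#'
#' Allele frequencies are computed on non-missing calls; a marker with no
#' calls at all is removed with its own reason code in the report.
#'
#' @param geno A `"geno"` object.
#' @param min_maf Minimum minor allele frequency (default 0.01).
#' @return Filtered `"geno"` with an updated QC report.
#' @export
filter_maf <- function(geno, min_maf = 0.01) {
  p <- .allele_freq(geno$dosages)
  all_missing <- is.nan(p) | is.na(p)
  geno2 <- .subset_geno(geno, cols = which(!all_missing))
  geno2 <- .log_stage(geno2, "all_missing", "markers", sum(all_missing))
  p <- p[!all_missing]
  keep <- pmin(p, 1 - p) >= min_maf
  geno2 <- .subset_geno(geno2, cols = which(keep))
  .log_stage(geno2, "maf", "markers", sum(!keep))
}

#' Remove markers deviating from Hardy-Weinberg heterozygosity
#'
#' Compares the observed heterozygote fraction with the Hardy-Weinberg
#' expectation `2p(1-p)` and removes markers whose absolute deviation exceeds
#' `max_dev`.
#'
#' @param geno A `"geno"` object.
#' @param max_dev Maximum tolerated `|obs_het - 2p(1-p)|` (default 0.15).
#' @return Filtered `"geno"` with an updated QC report.
#' @export
filter_het_deviation <- function(geno, max_dev = 0.15) {
  p <- .allele_freq(geno$dosages)
  obs_het <- colMeans(geno$dosages == 1, na.rm = TRUE)
  dev <- abs(obs_het - 2 * p * (1 - p))
  keep <- !is.na(dev) & dev <= max_dev
  geno2 <- .subset_geno(geno, cols = which(keep))
  .log_stage(geno2, "het_deviation", "markers", sum(!keep))
}

#' Remove markers with missing or duplicated genomic positions
#'
#' A marker with a missing or non-positive bp position is removed; for
#' markers sharing a (chromosome, position) pair only the first in file order
#' is kept.
#'
#' @param geno A `"geno"` object.
#' @return Filtered `"geno"` with an updated QC report.
#' @export
filter_positions <- function(geno) {
  map <- geno$map
  has_pos <- !is.na(map$pos) & !is.na(map$chrom) & map$pos > 0
  geno2 <- .subset_geno(geno, cols = which(has_pos))
  geno2 <- .log_stage(geno2, "missing_position", "markers", sum(!has_pos))
  map2 <- geno2$map
  dup <- duplicated(paste(map2$chrom, map2$pos))
  geno2 <- .subset_geno(geno2, cols = which(!dup))
  .log_stage(geno2, "duplicated_position", "markers", sum(dup))
}

#' Drop genotyped individuals that have no phenotypic record
#'
#' Matching is by exact string equality of ids; unmatched genotyped ids are
#' removed and counted.
#'
#' @param geno A `"geno"` object.
#' @param phenotype_ids Character vector of ids present in the phenotype
#'   table.
#' @return Filtered `"geno"` with an updated QC report.
#' @export
drop_unphenotyped <- function(geno, phenotype_ids) {
  keep <- rownames(geno$dosages) %in% as.character(phenotype_ids)
  if (!any(keep)) {
    stop("no genotyped individual has a phenotypic record", call. = FALSE)
  }
  geno2 <- .subset_geno(geno, rows = which(keep))
  .log_stage(geno2, "unphenotyped", "individuals", sum(!keep))
}

#' Run the full marker/individual quality-control pipeline
#'
#' Applies, in order: call-rate filtering (markers then individuals), minor
#' allele frequency, heterozygosity deviation, position validity/duplication,
#' and (optionally) removal of unphenotyped individuals. Frequencies are
#' recomputed at each stage on the retained data.
#'
#' @param geno A `"geno"` object.
#' @param call_rate,maf,het_dev Filter thresholds; see the individual filters.
#' @param phenotype_ids Optional id vector for [drop_unphenotyped()].
#' @return Filtered `"geno"`; inspect removals with [qc_report()].
#' @export
run_qc <- function(geno, call_rate = 0.90, maf = 0.01, het_dev = 0.15,
                   phenotype_ids = NULL) {
  geno <- filter_call_rate(geno, call_rate)
  geno <- filter_maf(geno, maf)
  geno <- filter_het_deviation(geno, het_dev)
  geno <- filter_positions(geno)
  if (!is.null(phenotype_ids)) geno <- drop_unphenotyped(geno, phenotype_ids)
  geno
}

#' Read genotypes from PLINK text files (.ped/.map)
#'
#' Parses the white-space separated text dialect: the `.map` file gives
#' chromosome, marker id, genetic distance and bp position; the `.ped` file
#' gives six id columns followed by two allele calls per marker (`0` =
#' missing). Dosages count copies of the first allele observed for each
#' marker, which is recorded as `a1` in the map.
#'
#' @param prefix Path prefix; `<prefix>.ped` and `<prefix>.map` must exist.
#' @return A `"geno"` object.
#' @export
read_plink_ped <- function(prefix) {
  map_path <- paste0(prefix, ".map")
  ped_path <- paste0(prefix, ".ped")
  map_raw <- utils::read.table(map_path, header = FALSE,
                               col.names = c("chrom", "marker", "cm", "pos"),
                               colClasses = c("character", "character",
                                              "numeric", "integer"))
  ped_raw <- utils::read.table(ped_path, header = FALSE,
                               colClasses = "character")
  m <- nrow(map_raw)
  if (ncol(ped_raw) != 6 + 2 * m) {
    stop(".ped has ", ncol(ped_raw), " columns; expected ", 6 + 2 * m,
         " for ", m, " markers", call. = FALSE)
  }
  ids <- ped_raw[[2]]
  n <- nrow(ped_raw)
  dos <- matrix(NA_real_, n, m, dimnames = list(ids, map_raw$marker))
  a1 <- a2 <- rep(NA_character_, m)
  for (j in seq_len(m)) {
    al <- cbind(ped_raw[[6 + 2 * j - 1]], ped_raw[[6 + 2 * j]])
    al[al == "0"] <- NA
    seen <- unique(stats::na.omit(as.vector(al)))
    if (length(seen) > 2) {
      stop("marker ", map_raw$marker[j], " has >2 alleles", call. = FALSE)
    }
    a1[j] <- if (length(seen) >= 1) seen[1] else NA_character_
    a2[j] <- if (length(seen) == 2) seen[2] else NA_character_
    miss <- is.na(al[, 1]) | is.na(al[, 2])
    d <- (al[, 1] == a1[j]) + (al[, 2] == a1[j])
    d[miss] <- NA
    dos[, j] <- d
  }
  map <- tibble::tibble(marker = map_raw$marker, chrom = map_raw$chrom,
                        pos = map_raw$pos, a1 = a1, a2 = a2)
  genotypes(dos, map)
}

#' Write genotypes to PLINK text files (.ped/.map)
#'
#' @param geno A `"geno"` object. Markers without recorded alleles are written
#'   with alleles `A`/`B`.
#' @param prefix Output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_plink_ped <- function(geno, prefix) {
  map <- geno$map
  a1 <- if ("a1" %in% names(map)) map$a1 else rep(NA_character_, nrow(map))
  a2 <- if ("a2" %in% names(map)) map$a2 else rep(NA_character_, nrow(map))
  a1[is.na(a1)] <- "A"
  a2[is.na(a2)] <- "B"
  utils::write.table(
    data.frame(map$chrom, map$marker, 0, map$pos),
    paste0(prefix, ".map"), quote = FALSE, row.names = FALSE,
    col.names = FALSE, sep = "\t")
  n <- nrow(geno$dosages)
  m <- ncol(geno$dosages)
  allele_block <- matrix("0", n, 2 * m)
  for (j in seq_len(m)) {
    d <- geno$dosages[, j]
    first <- ifelse(is.na(d), "0", ifelse(d >= 1, a1[j], a2[j]))
    second <- ifelse(is.na(d), "0", ifelse(d == 2, a1[j], a2[j]))
    allele_block[, 2 * j - 1] <- first
    allele_block[, 2 * j] <- second
  }
  ids <- rownames(geno$dosages)
  ped <- cbind(ids, ids, "0", "0", "0", "-9", allele_block)
  utils::write.table(ped, paste0(prefix, ".ped"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE, sep = " ")
  invisible(prefix)
}
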
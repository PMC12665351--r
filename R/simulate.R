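#' Simulate biallelic SNP genotypes in Hardy-Weinberg equilibrium
#'
#' Marker allele frequencies are drawn uniformly from `maf_range` and dosages
#' sampled binomially; markers are placed at distinct uniform bp positions on
#' equally sized chromosomes.
#'
#' @param n_individuals,n_markers Dimensions of the panel.
#' @param n_chromosomes Number of chromosomes (markers split evenly).
#' @param maf_range Lower/upper bound of the allele-frequency draw (default
#'   `c(0.01, 0.5)`).
#' @param missing_rate Fraction of calls set to missing at random (default
#'   0).
#' @param chrom_length_bp Chromosome length in bp (default 1e8, i.e. 1 Morgan
#'   at 1 cM/Mb).
#' @param seed Optional integer seed; the output is a pure function of the
#'   arguments and the seed.
#' @return A `"geno"` object; the drawing frequencies are stored in the map
#'   column `p_true`.
#' @export
simulate_genotypes <- function(n_individuals, n_markers, n_chromosomes = 5,
                               maf_range = c(0.01, 0.5), missing_rate = 0,
                               chrom_length_bp = 1e8, seed = NULL) {
  if (n_markers < n_chromosomes) {
    stop("need at least one marker per chromosome", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  p <- stats::runif(n_markers, maf_range[1], maf_range[2])
  dos <- matrix(stats::rbinom(n_individuals * n_markers, 2,
                              rep(p, each = n_individuals)),
                n_individuals, n_markers)
  if (missing_rate > 0) {
    dos[stats::runif(length(dos)) < missing_rate] <- NA
  }
  rownames(dos) <- sprintf("sow%04d", seq_len(n_individuals))
  chrom <- sort(rep_len(seq_len(n_chromosomes), n_markers))
  pos <- integer(n_markers)
  for (cc in seq_len(n_chromosomes)) {
    idx <- which(chrom == cc)
    pos[idx] <- sort(sample.int(chrom_length_bp, length(idx)))
  }
  map <- tibble::tibble(
    marker = sprintf("snp%05d", seq_len(n_markers)),
    chrom = paste0("chr", chrom), pos = pos, p_true = p
  )
  genotypes(dos, map)
}

#' Simulate phenotypes with known genetic architecture
#'
#' Builds additive genetic values from per-marker effects (an infinitesimal
#' polygenic background, optionally plus planted QTL of specified variance
#' fractions), with a requested genetic-correlation structure across traits,
#' then adds contemporary-group effects, permanent environmental effects for
#' repeated-record traits, and residuals. The polygenic values are rescaled
#' so each trait's realized additive variance matches its target exactly; the
#' full realized components are returned as ground truth.
#'
#' @param geno A `"geno"` object (complete or missing-at-random dosages).
#' @param h2 Named numeric vector of target heritabilities, one per trait.
#' @param rg Genetic correlation matrix across traits (default identity);
#'   unit diagonal, positive semidefinite.
#' @param pe_fraction Named vector of permanent-environment variance
#'   fractions (0 for single-record traits; default all 0).
#' @param n_records Records per individual (scalar or named per trait;
#'   traits with `n_records > 1` get fresh residuals per record).
#' @param planted_qtl Named list per trait of data frames with columns
#'   `marker` (column index) and `var_frac` (fraction of phenotypic variance;
#'   effect signs alternate).
#' @param n_groups Number of contemporary groups (default 10; 1 disables).
#' @param group_sd SD of group effects on each trait (default 0.5).
#' @param sigma2_p Phenotypic variance per trait (scalar or named; default
#'   1).
#' @param seed Optional integer seed.
#' @return List with `phenotypes` (tibble: `sow_id`, `record`, `group`, one
#'   column per trait) and `truth` (list: additive-value matrix `a`, marker
#'   effects `marker_effects`, `pe`, `group_effects`, and the realized
#'   parameters).
#' @export
simulate_phenotypes <- function(geno, h2, rg = NULL, pe_fraction = NULL,
                                n_records = 1, planted_qtl = NULL,
                                n_groups = 10, group_sd = 0.5, sigma2_p = 1,
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  traits <- names(h2)
  if (is.null(traits)) {
    traits <- paste0("trait", seq_along(h2))
    names(h2) <- traits
  }
  tn <- length(traits)
  if (is.null(rg)) rg <- diag(tn)
  stopifnot(nrow(rg) == tn, all(abs(diag(rg) - 1) < 1e-8))
  if (is.null(pe_fraction)) pe_fraction <- stats::setNames(rep(0, tn), traits)
  pe_fraction <- pe_fraction[traits]
  pe_fraction[is.na(pe_fraction)] <- 0
  sigma2_p <- if (length(sigma2_p) == 1) {
    stats::setNames(rep(sigma2_p, tn), traits)
  } else sigma2_p[traits]
  if (any(h2 + pe_fraction >= 1)) {
    stop("h2 + pe_fraction must be < 1 for every trait", call. = FALSE)
  }
  n_records <- if (length(n_records) == 1) {
    stats::setNames(rep(n_records, tn), traits)
  } else n_records[traits]

  M <- geno$dosages
  n <- nrow(M)
  m <- ncol(M)
  p <- colMeans(M, na.rm = TRUE) / 2
  Z <- sweep(M, 2, 2 * p)
  Z[is.na(Z)] <- 0

  sigma2_a <- h2 * sigma2_p
  qtl_var <- stats::setNames(rep(0, tn), traits)
  B_qtl <- matrix(0, m, tn, dimnames = list(geno$map$marker, traits))
  for (tr in names(planted_qtl %||% list())) {
    q <- planted_qtl[[tr]]
    for (i in seq_len(nrow(q))) {
      j <- q$marker[i]
      vf <- q$var_frac[i]
      sgn <- if (i %% 2 == 0) -1 else 1
      B_qtl[j, tr] <- sgn * sqrt(vf * sigma2_p[tr] / (2 * p[j] * (1 - p[j])))
      qtl_var[tr] <- qtl_var[tr] + vf * sigma2_p[tr]
    }
  }
  sigma2_poly <- sigma2_a - qtl_var
  if (any(sigma2_poly < 0)) {
    stop("planted QTL variance exceeds the additive target", call. = FALSE)
  }
  denom <- 2 * sum(p * (1 - p))
  sd_poly <- sqrt(sigma2_poly)
  Cov <- (rg * tcrossprod(sd_poly)) / denom
  ch <- chol(Cov + diag(1e-12, tn))
  B_poly <- matrix(stats::rnorm(m * tn), m, tn) %*% ch
  a_poly <- Z %*% B_poly
  # rescale so the realized polygenic variance hits the target exactly
  scl <- sqrt(sigma2_poly / pmax(apply(a_poly, 2, stats::var), 1e-12))
  scl[sigma2_poly == 0] <- 0
  a_poly <- sweep(a_poly, 2, scl, `*`)
  B_poly <- sweep(B_poly, 2, scl, `*`)
  a <- a_poly + Z %*% B_qtl
  colnames(a) <- traits
  rownames(a) <- rownames(M)

  group <- if (n_groups > 1) {
    sample(rep_len(seq_len(n_groups), n))
  } else rep(1L, n)
  group_eff <- matrix(stats::rnorm(n_groups * tn, 0, group_sd), n_groups, tn,
                      dimnames = list(NULL, traits))
  if (n_groups == 1) group_eff[] <- 0
  pe <- matrix(0, n, tn, dimnames = list(rownames(M), traits))
  for (tr in traits) {
    if (pe_fraction[tr] > 0) {
      pe[, tr] <- stats::rnorm(n, 0, sqrt(pe_fraction[tr] * sigma2_p[tr]))
    }
  }

  rows <- list()
  for (tr in traits) {
    s2e <- (1 - h2[tr] - pe_fraction[tr]) * sigma2_p[tr]
    for (rec in seq_len(n_records[tr])) {
      y <- a[, tr] + pe[, tr] + group_eff[group, tr] +
        stats::rnorm(n, 0, sqrt(s2e))
      rows[[paste(tr, rec)]] <- tibble::tibble(
        sow_id = rownames(M), record = rec, group = factor(group),
        trait = tr, value = y)
    }
  }
  phen <- dplyr::bind_rows(rows) |>
    tidyr::pivot_wider(names_from = "trait", values_from = "value")

  list(
    phenotypes = phen,
    truth = list(
      a = a, marker_effects = B_poly + B_qtl, pe = pe,
      group = group, group_effects = group_eff,
      params = list(h2 = h2, rg = rg, pe_fraction = pe_fraction,
                    sigma2_p = sigma2_p, n_records = n_records,
                    planted_qtl = planted_qtl)
    )
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Generate ethogram sessions from latent reactivity
#'
#' Deterministically maps one latent reactivity value per sow (additive
#' genetic value plus environmental noise, supplied by the caller) onto the
#' observation scale of the shaving test: postures at the three time points
#' by ordered thresholding with time-point shifts, per-stage vocalization
#' scores by ordered thresholding toward higher alertness, shave time as a
#' log-normal transform with log-scale SD 0.45 around 50 s (reproducing the
#' observed right skew), and the intervention moment by reactivity quantiles
#' (about 44% of sows need none; about 10% need repositioning before the
#' first site). Because the map is deterministic, a zero-variance latent
#' vector yields identical sessions for every sow.
#'
#' @param latent Numeric vector of latent reactivity values, one per sow
#'   (names used as `sow_id` if present).
#' @param n_weeks Number of shaving weeks used as contemporary groups.
#' @return Sessions tibble in the format consumed by [score_sessions()].
#' @export
simulate_ethogram_sessions <- function(latent, n_weeks = 6) {
  n <- length(latent)
  ids <- names(latent) %||% sprintf("sow%04d", seq_len(n))
  s <- stats::sd(latent)
  l <- if (isTRUE(s > 0)) (latent - mean(latent)) / s else rep(0, n)

  posture_cut <- function(x) {
    cut(x, c(-Inf, -1, 0, 1, Inf), labels = names(posture_levels))
  }
  p1 <- posture_cut(l - 0.8) # before contact: mostly lying
  p2 <- posture_cut(l)
  p3 <- posture_cut(l + 0.3)

  # intervention moment by reactivity quantile (none ~44%, before-first ~10%)
  interv <- cut(l, c(-Inf, stats::qnorm(0.442), stats::qnorm(0.901), Inf),
                labels = c("none", "between_sites", "before_first_site"))

  score_to_subset <- c("NONE", "SGT", "SGT+LGT", "LGT", "SGT+LGT+BRK", "SGT+BRK",
                       "LGT+BRK", "BRK")
  stage_breaks <- c(-Inf, 0, 0.9, 1.5, 2.0, 2.4, 2.8, 3.2, Inf)
  stage_subset <- function(x) {
    score_to_subset[as.integer(cut(x, stage_breaks))]
  }
  voc1 <- stage_subset(l - 0.5) # pre-contact stage is quieter
  voc2 <- stage_subset(l)
  voc3 <- ifelse(interv == "none", NA_character_, stage_subset(l + 0.2))
  voc4 <- stage_subset(l + 0.1)

  st <- exp(log(50) + 0.45 * l)
  touches <- pmax(0L, as.integer(round(1 + l)))

  tibble::tibble(
    sow_id = ids,
    posture_1 = as.character(p1), posture_2 = as.character(p2),
    posture_3 = as.character(p3),
    voc_1 = voc1, voc_2 = voc2, voc_3 = voc3, voc_4 = voc4,
    shave_time_s = st,
    touches = touches,
    intervention_moment = as.character(interv),
    hair_density = 2L,
    contemporary_group = paste0("week", rep_len(seq_len(n_weeks), n))
  )
}
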
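#' Back-solve posterior GEBV draws into per-SNP effect draws
#'
#' For each retained posterior draw of the additive effects `u`, the
#' allele-substitution effects are `g = Z' Ginv u / (2 * sum(p(1-p)))`, with
#' `Z` the dosage matrix centered at `2p` and `Ginv` the inverse of the
#' (stabilized) genomic relationship matrix the model was fitted with.
#' Per-marker posterior means and standard deviations are returned.
#'
#' @param fit A `"reactigen_fit"` from a single-trait or repeatability model
#'   (for a two-trait fit pass `fit$a_draws$trait1` etc. through `a_draws`).
#' @param geno The QC-passed `"geno"` the GRM was built from (same
#'   individuals, same order).
#' @param grm The stabilized `"grm"` used in the fit.
#' @param a_draws Optional individuals x draws matrix overriding
#'   `fit$a_draws`.
#' @param sigma2_a,sigma2_e,sigma2_pe Posterior-mean variance components used
#'   for the effects' sampling standard error (defaults: taken from
#'   `fit$samples`).
#' @param X,id_index Fixed-effect design and record-to-individual index used
#'   in the fit (defaults: taken from the fit; must be supplied when
#'   back-solving one trait of a two-trait fit).
#' @return Tibble with one row per marker: `marker`, `chrom`, `pos`, `freq`,
#'   `effect` (posterior mean), `effect_psd` (posterior SD) and `effect_se`,
#'   the sampling standard error of the back-solved effect. The posterior SD
#'   of a weakly informed marker stays close to its prior SD, so the naive
#'   posterior z-statistic is deflated; the calibrated statistic instead
#'   divides by the estimator's sampling SD, whose variance is
#'   `diag(Zc' Ginv (sigma2_a G - Caa) Ginv Zc) / denom^2` with `Caa` the
#'   prediction-error covariance of the GEBVs evaluated at the
#'   posterior-mean variance components (fixed effects absorbed).
#' @export
backsolve_snp_effects <- function(fit, geno, grm, a_draws = NULL,
                                  sigma2_a = NULL, sigma2_e = NULL,
                                  sigma2_pe = NULL, X = NULL,
                                  id_index = NULL) {
  if (is.null(a_draws)) {
    a_draws <- fit$a_draws
    if (is.list(a_draws)) {
      stop("two-trait fit: pass one trait's draws via `a_draws`",
           call. = FALSE)
    }
  }
  post_mean <- function(cols) {
    col <- intersect(cols, names(fit$samples))[1]
    if (is.na(col)) return(NULL)
    mean(fit$samples[[col]])
  }
  if (is.null(sigma2_a)) sigma2_a <- post_mean(c("sigma2_a", "sigma2_a1"))
  if (is.null(sigma2_e)) sigma2_e <- post_mean(c("sigma2_e", "sigma2_e1"))
  if (is.null(sigma2_pe)) sigma2_pe <- post_mean("sigma2_pe") %||% 0
  if (is.null(X)) X <- fit$X
  if (is.null(id_index)) id_index <- fit$id_index
  if (is.null(sigma2_a) || is.null(sigma2_e) || is.list(X) || is.null(X)) {
    stop("supply sigma2_a, sigma2_e and X explicitly for this fit type",
         call. = FALSE)
  }
  M <- geno$dosages
  if (nrow(M) != nrow(grm$G) ||
      !identical(rownames(M), rownames(grm$G))) {
    stop("genotype individuals do not match the GRM", call. = FALSE)
  }
  if (!is.null(rownames(a_draws)) &&
      !identical(rownames(a_draws), rownames(grm$G))) {
    stop("GEBV draws do not match the GRM individuals", call. = FALSE)
  }
  p <- grm$p
  if (!is.null(p) && !is.null(names(p)) &&
      all(geno$map$marker %in% names(p))) {
    p <- p[geno$map$marker] # align to this panel's marker order
  } else {
    p <- colMeans(M, na.rm = TRUE) / 2
  }
  Z <- sweep(M, 2, 2 * p)
  Z[is.na(Z)] <- 0
  denom <- grm$denom
  if (is.null(denom)) denom <- 2 * sum(p * (1 - p))
  ch <- chol(grm$G)
  Ginv_u <- .chol_solve(ch, a_draws)
  eff_draws <- crossprod(Z, Ginv_u) / denom
  GinvZ <- .chol_solve(ch, Z)
  var_g <- .effect_sampling_var(grm$G, GinvZ, denom, X, id_index,
                                sigma2_a, sigma2_e, sigma2_pe)
  psd <- apply(eff_draws, 1, stats::sd)
  tibble::tibble(
    marker = geno$map$marker,
    chrom = geno$map$chrom,
    pos = geno$map$pos,
    freq = unname(p),
    effect = rowMeans(eff_draws),
    effect_psd = psd,
    effect_se = sqrt(pmax(var_g, 0))
  )
}

.chol_solve <- function(ch, B) {
  backsolve(ch, forwardsolve(t(ch), B))
}

# sampling variance of the back-solved effects at fixed (posterior mean)
# variance components: Var(g_hat) = D' (sigma2_a G - Caa) D, D = Ginv Zc /
# denom, Caa the GEBV prediction-error covariance with fixed effects
# absorbed. Repeated records enter through V = sigma2_e I + sigma2_pe Z Z'
# (Woodbury at the individual level).
.effect_sampling_var <- function(G, GinvZ, denom, X, id_index,
                                 sigma2_a, sigma2_e, sigma2_pe) {
  n <- nrow(G)
  counts <- tabulate(id_index, n)
  w <- counts / (sigma2_e + counts * sigma2_pe)
  ZtX <- rowsum(X, group = id_index)
  ZtX_full <- matrix(0, n, ncol(X))
  ZtX_full[as.integer(rownames(ZtX)), ] <- ZtX
  ZtVinvX <- ZtX_full / (sigma2_e + counts * sigma2_pe)
  XtVinvX <- crossprod(X) / sigma2_e -
    crossprod(ZtX_full, ZtX_full * (sigma2_pe /
                                      (sigma2_e *
                                         (sigma2_e + counts * sigma2_pe))))
  info_a <- diag(w, n) - ZtVinvX %*% solve(XtVinvX, t(ZtVinvX))
  Caa <- solve(info_a + solve(G) / sigma2_a)
  S <- sigma2_a * G - Caa
  colSums(GinvZ * (S %*% GinvZ)) / denom^2
}

#' Approximate per-SNP p-values from back-solved effects
#'
#' Treats each marker's z-statistic -- the back-solved effect over its
#' sampling standard error (`effect_se` when present, falling back to the
#' posterior SD) -- as standard normal under the null and takes the two-sided
#' tail. Markers with a zero standard error carry no information and get
#' `p = 1` with a flag.
#'
#' @param effects Tibble from [backsolve_snp_effects()] (columns `effect` and
#'   `effect_se` or `effect_psd`).
#' @return The tibble with added `z`, `p_value` and `unidentified` columns.
#' @export
approx_pvalues <- function(effects) {
  se <- if ("effect_se" %in% names(effects)) effects$effect_se else
    effects$effect_psd
  z <- ifelse(se > 0, effects$effect / se, 0)
  dplyr::mutate(effects,
                z = z,
                p_value = ifelse(se > 0, 2 * stats::pnorm(-abs(z)), 1),
                unidentified = se <= 0)
}

#' Phenotypic variance explained by one marker
#'
#' `2 p (1 - p) effect^2 / total_variance` under Hardy-Weinberg; the
#' denominator is configurable (phenotypic by convention, additive if
#' preferred).
#'
#' @param effect Allele-substitution effect(s).
#' @param p Allele frequency(ies) strictly inside (0, 1).
#' @param total_variance Positive denominator variance.
#' @return Fraction(s) of variance explained.
#' @export
variance_explained <- function(effect, p, total_variance) {
  if (any(p <= 0 | p >= 1)) {
    stop("monomorphic marker (p = 0 or 1) reached variance_explained(); ",
         "it should have been removed in QC", call. = FALSE)
  }
  stopifnot(total_variance > 0)
  2 * p * (1 - p) * effect^2 / total_variance
}

#' Chromosome-wise significance thresholds from independent segments
#'
#' The effective number of independent chromosome segments is
#' `Me = 2 Ne L / log(Ne L)` with `Ne` the effective population size and `L`
#' the chromosome length in Morgans (natural log by default); the
#' chromosome-wise Bonferroni threshold is `alpha / Me`. Chromosome lengths
#' are taken as the marker span converted at `cm_per_mb`.
#'
#' @param map Marker map tibble (`chrom`, `pos`).
#' @param Ne Effective population size (default 100).
#' @param alpha Genome-wide error rate per chromosome (default 0.05).
#' @param cm_per_mb Map-distance conversion (default 1 cM/Mb).
#' @param log_base Base of the logarithm in `Me` (default `exp(1)`).
#' @return Tibble with one row per chromosome: `chrom`, `L_morgan`, `Me`,
#'   `threshold`.
#' @export
me_thresholds <- function(map, Ne = 100, alpha = 0.05, cm_per_mb = 1,
                          log_base = exp(1)) {
  dplyr::group_by(tibble::as_tibble(map), .data$chrom) |>
    dplyr::summarise(span_bp = max(.data$pos) - min(.data$pos),
                     .groups = "drop") |>
    dplyr::mutate(
      L_morgan = .data$span_bp * 1e-6 * cm_per_mb / 100,
      Me = {
        if (any(.data$span_bp <= 0)) {
          stop("chromosome with zero marker span (single marker?)",
               call. = FALSE)
        }
        NeL <- Ne * .data$L_morgan
        if (any(NeL <= 1)) {
          stop("Ne * L <= 1 gives a non-positive log in Me", call. = FALSE)
        }
        2 * NeL / (log(NeL) / log(log_base))
      },
      threshold = alpha / .data$Me
    ) |>
    dplyr::select("chrom", "L_morgan", "Me", "threshold")
}

#' Genomic inflation factor
#'
#' `lambda = median(qchisq(p, df = 1, lower = FALSE)) / qchisq(0.5, 1)`:
#' the ratio of the median association chi-square to its null median
#' (0.4549); values near 1 indicate calibrated tests.
#'
#' @param p_values Vector of at least 100 p-values in (0, 1].
#' @return Numeric lambda.
#' @export
genomic_inflation <- function(p_values) {
  if (length(p_values) < 100) {
    stop("need at least 100 p-values", call. = FALSE)
  }
  if (any(p_values <= 0 | p_values > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  chisq <- stats::qchisq(p_values, df = 1, lower.tail = FALSE)
  stats::median(chisq) / stats::qchisq(0.5, df = 1)
}

#' Candidate genomic windows around significant markers
#'
#' Flanks each significant marker by `flank_bp` on both sides (clamped at the
#' chromosome start) and merges overlapping same-chromosome windows.
#' Intervals are 0-based half-open, ready for BED output.
#'
#' @param results Tibble with `chrom`, `pos` and `significant` columns (or
#'   any marker table; rows where `significant` is `TRUE` are used, all rows
#'   if the column is absent).
#' @param flank_bp Flank size in bp (default 100,000).
#' @return Tibble of merged windows: `chrom`, `start`, `end`, `n_markers`.
#' @export
candidate_windows <- function(results, flank_bp = 1e5) {
  stopifnot(flank_bp >= 0)
  hits <- if ("significant" %in% names(results)) {
    dplyr::filter(results, .data$significant)
  } else results
  if (nrow(hits) == 0) {
    return(tibble::tibble(chrom = character(0), start = numeric(0),
                          end = numeric(0), n_markers = integer(0)))
  }
  hits |>
    dplyr::mutate(start = pmax(0, .data$pos - flank_bp),
                  end = .data$pos + flank_bp) |>
    dplyr::arrange(.data$chrom, .data$start) |>
    dplyr::group_by(.data$chrom) |>
    dplyr::mutate(new_block = cumsum(
      dplyr::lag(cummax(.data$end), default = -Inf) < .data$start)) |>
    dplyr::group_by(.data$chrom, .data$new_block) |>
    dplyr::summarise(start = min(.data$start), end = max(.data$end),
                     n_markers = dplyr::n(), .groups = "drop") |>
    dplyr::select("chrom", "start", "end", "n_markers")
}

#' Write candidate windows as a BED file
#'
#' @param windows Tibble from [candidate_windows()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(windows, path) {
  utils::write.table(
    windows[c("chrom", "start", "end")], path, sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' GWAS by back-solving GEBVs into SNP effects
#'
#' End-to-end association scan for one fitted trait: back-solve the posterior
#' GEBV draws to marker effects, form approximate p-values from the posterior
#' z-statistics, compute the variance explained by each marker, apply
#' chromosome-wise `alpha / Me` thresholds, and record the genomic inflation
#' factor.
#'
#' @inheritParams backsolve_snp_effects
#' @inheritParams me_thresholds
#' @param total_variance Denominator for the variance explained; default is
#'   the posterior-mean phenotypic variance of the fit.
#' @return A tibble of class `"reactigen_gwas"`: per-marker `effect`,
#'   `effect_psd`, `z`, `p_value`, `variance_explained`, `threshold`,
#'   `significant`; attributes `lambda` and `thresholds` carry the inflation
#'   factor and the per-chromosome scheme.
#' @export
run_gwas <- function(fit, geno, grm, Ne = 100, alpha = 0.05, cm_per_mb = 1,
                     total_variance = NULL, a_draws = NULL) {
  eff <- backsolve_snp_effects(fit, geno, grm, a_draws = a_draws)
  eff <- approx_pvalues(eff)
  if (is.null(total_variance)) {
    sm <- summarize_fit(fit)
    total_variance <- sm$mean[match("sigma2_p", sm$component)]
    if (is.na(total_variance)) {
      stop("supply total_variance explicitly for this fit type",
           call. = FALSE)
    }
  }
  eff$variance_explained <- variance_explained(eff$effect, eff$freq,
                                               total_variance)
  thr <- me_thresholds(geno$map, Ne = Ne, alpha = alpha,
                       cm_per_mb = cm_per_mb)
  eff <- dplyr::left_join(eff, thr[c("chrom", "threshold")], by = "chrom")
  eff$significant <- eff$p_value < eff$threshold
  lambda <- genomic_inflation(eff$p_value)
  structure(eff, lambda = lambda, thresholds = thr,
            class = c("reactigen_gwas", class(eff)))
}

#' Manhattan plot of a GWAS result
#'
#' @param object A `"reactigen_gwas"`.
#' @param ... Unused.
#' @return A ggplot object; chromosome-wise significance thresholds are drawn
#'   as segments and significant markers highlighted.
#' @exportS3Method ggplot2::autoplot
autoplot.reactigen_gwas <- function(object, ...) {
  df <- tibble::as_tibble(object) |>
    dplyr::arrange(.data$chrom, .data$pos) |>
    dplyr::group_by(.data$chrom) |>
    dplyr::mutate(rel = .data$pos - min(.data$pos)) |>
    dplyr::ungroup()
  offsets <- df |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(w = max(.data$rel) + 1, .groups = "drop") |>
    dplyr::mutate(offset = dplyr::lag(cumsum(.data$w), default = 0))
  df <- dplyr::left_join(df, offsets, by = "chrom") |>
    dplyr::mutate(x = .data$rel + .data$offset,
                  chrom_parity = factor(as.integer(factor(.data$chrom)) %% 2))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x,
                                   y = -log10(.data$p_value))) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$chrom_parity),
                        size = 0.6, show.legend = FALSE) +
    ggplot2::geom_point(data = dplyr::filter(df, .data$significant),
                        colour = "red", size = 1.2) +
    ggplot2::scale_colour_manual(values = c("grey30", "grey60")) +
    ggplot2::labs(x = "Genome position", y = expression(-log[10](p))) +
    ggplot2::theme_minimal()
}
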
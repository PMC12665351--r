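#' Genomic relationship matrix (VanRaden method 1)
#'
#' Builds `G = Z Z' / (2 * sum(p * (1 - p)))` from 0/1/2 dosages, where `Z` is
#' the dosage matrix centered at twice the observed allele frequencies.
#' Missing dosages are mean-imputed at `2p` per marker (so they contribute 0
#' after centering). Allele frequencies are computed from the analyzed sample.
#'
#' @param geno A `"geno"` object or a plain individuals x markers dosage
#'   matrix.
#' @return Object of class `"grm"`: list with `G` (symmetric n x n matrix with
#'   id dimnames), `p` (per-marker allele frequencies), `denom`
#'   (`2 * sum(p*(1-p))`) and `epsilon` (stabilization blend applied so far,
#'   initially 0).
#' @export
grm_vanraden <- function(geno) {
  M <- if (inherits(geno, "geno")) geno$dosages else as.matrix(geno)
  p <- colMeans(M, na.rm = TRUE) / 2
  names(p) <- colnames(M)
  poly <- !is.na(p) & p > 0 & p < 1
  denom <- 2 * sum(p[poly] * (1 - p[poly]))
  if (!isTRUE(denom > 0)) {
    stop("all markers monomorphic: VanRaden denominator is 0", call. = FALSE)
  }
  Z <- sweep(M, 2, 2 * p)
  Z[is.na(Z)] <- 0 # mean imputation at 2p
  G <- tcrossprod(Z[, poly, drop = FALSE]) / denom
  G <- (G + t(G)) / 2
  dimnames(G) <- list(rownames(M), rownames(M))
  structure(list(G = G, p = p, denom = denom, epsilon = 0), class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat("<grm> ", nrow(x$G), " individuals; mean diagonal ",
      signif(mean(diag(x$G)), 4), "; epsilon ", x$epsilon, "\n", sep = "")
  invisible(x)
}

#' @export
dim.grm <- function(x) dim(x$G)

#' Stabilize a genomic relationship matrix
#'
#' Blends the matrix with the identity, `G* = (1 - epsilon) G + epsilon I`,
#' guaranteeing an invertible covariance kernel for the Gibbs sampler and the
#' SNP-effect back-solve (this population has no pedigree to blend with).
#'
#' @param grm A `"grm"` object (or bare symmetric matrix).
#' @param epsilon Blend weight on the identity, in `[0, 1]` (default 0.01).
#' @return The `"grm"` with `G` replaced by the blend and `epsilon` recorded.
#' @export
grm_stabilize <- function(grm, epsilon = 0.01) {
  stopifnot(epsilon >= 0, epsilon <= 1)
  bare <- !inherits(grm, "grm")
  G <- if (bare) grm else grm$G
  if (!isSymmetric(unname(G), tol = 1e-8)) {
    stop("stabilize() requires a symmetric matrix", call. = FALSE)
  }
  Gs <- (1 - epsilon) * G + epsilon * diag(nrow(G))
  dimnames(Gs) <- dimnames(G)
  if (bare) {
    structure(list(G = Gs, p = NULL, denom = NULL, epsilon = epsilon),
              class = "grm")
  } else {
    grm$G <- Gs
    grm$epsilon <- grm$epsilon + epsilon
    grm
  }
}

#' Distribution of pairwise genomic relationship coefficients
#'
#' Extracts the upper triangle of G (excluding the diagonal) and summarizes
#' the degree of relatedness in the population.
#'
#' @param grm A `"grm"` object.
#' @param breaks Number of histogram bins (default 60).
#' @return List with `values` (the n(n-1)/2 coefficients), `summary` (tibble:
#'   n_pairs, mean, sd, quantiles) and `histogram` (tibble: bin mid-points and
#'   counts).
#' @export
relationship_distribution <- function(grm, breaks = 60) {
  G <- grm$G
  if (nrow(G) < 2) stop("need at least 2 individuals", call. = FALSE)
  v <- G[upper.tri(G)]
  q <- stats::quantile(v, c(0.025, 0.25, 0.5, 0.75, 0.975))
  h <- graphics::hist(v, breaks = breaks, plot = FALSE)
  list(
    values = v,
    summary = tibble::tibble(
      n_pairs = length(v), mean = mean(v), sd = stats::sd(v),
      q2.5 = q[[1]], q25 = q[[2]], median = q[[3]], q75 = q[[4]],
      q97.5 = q[[5]]
    ),
    histogram = tibble::tibble(mid = h$mids, count = h$counts)
  )
}

#' Write a genomic relationship matrix as text triplets
#'
#' Writes the lower triangle (including the diagonal) as tab-separated
#' `i j value` rows plus an `<path>.ids` index file mapping row numbers to
#' individual ids — the interchange format most mixed-model tools accept.
#'
#' @param grm A `"grm"` object.
#' @param path Output path for the triplet file.
#' @return `path`, invisibly.
#' @export
write_grm <- function(grm, path) {
  G <- grm$G
  idx <- which(lower.tri(G, diag = TRUE), arr.ind = TRUE)
  utils::write.table(
    data.frame(i = idx[, 1], j = idx[, 2], value = G[idx]),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  ids <- rownames(G)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(G)))
  writeLines(ids, paste0(path, ".ids"))
  invisible(path)
}

#' Histogram of pairwise genomic relationships
#'
#' @param grm A `"grm"` object.
#' @param breaks Number of bins.
#' @return A ggplot object.
#' @export
plot_relationship_distribution <- function(grm, breaks = 60) {
  rd <- relationship_distribution(grm, breaks)
  ggplot2::ggplot(tibble::tibble(g = rd$values), ggplot2::aes(x = .data$g)) +
    ggplot2::geom_histogram(bins = breaks, fill = "grey35") +
    ggplot2::labs(x = "Genomic relationship coefficient (off-diagonal)",
                  y = "Pairs") +
    ggplot2::theme_minimal()
}
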
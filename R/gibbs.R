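#' Settings for a Gibbs sampling run
#'
#' Defaults mirror a production chain (500,000 iterations, 150,000 burn-in,
#' thinning 80); analyses on small data typically scale these down through
#' this object rather than editing the samplers.
#'
#' @param iterations Total chain length.
#' @param burn_in Discarded initial iterations (`< iterations`).
#' @param thin Thinning interval; `floor((iterations - burn_in) / thin)` draws
#'   are retained and at least 100 are required.
#' @param seed Optional integer seed; a fixed seed makes the retained chain
#'   reproducible.
#' @param prior Variance-component prior, a list with elements `nu` (degrees
#'   of freedom) and `scale`: each variance gets a scaled inverse chi-square
#'   prior with those hyperparameters. The default `nu = -2, scale = 0` is
#'   flat on the variance; `nu = 4` with a data-scaled `scale` gives a weakly
#'   informative prior. For two-trait fits the covariance matrices get the
#'   matching inverse-Wishart form (`nu = -3`, zero scale matrix when flat).
#' @return Object of class `"gibbs_config"`.
#' @export
gibbs_config <- function(iterations = 500000, burn_in = 150000, thin = 80,
                         seed = NULL, prior = list(nu = -2, scale = 0)) {
  stopifnot(iterations >= 1, burn_in >= 0, burn_in < iterations, thin >= 1)
  retained <- floor((iterations - burn_in) / thin)
  if (retained < 100) {
    stop("chain settings retain only ", retained,
         " draws; at least 100 are required", call. = FALSE)
  }
  structure(list(iterations = as.integer(iterations),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 seed = seed, prior = prior, retained = retained),
            class = "gibbs_config")
}

.as_G <- function(G) {
  if (inherits(G, "grm")) G$G else as.matrix(G)
}

.as_id_index <- function(Z, n_ind, g_ids) {
  if (is.matrix(Z)) {
    if (any(rowSums(Z != 0) != 1) || !all(Z %in% c(0, 1))) {
      stop("Z must be a 0/1 incidence matrix with one 1 per row",
           call. = FALSE)
    }
    return(max.col(Z))
  }
  if (is.factor(Z) || is.character(Z)) {
    idx <- match(as.character(Z), g_ids)
    if (anyNA(idx)) {
      stop("record id(s) absent from G: ",
           paste(unique(as.character(Z)[is.na(idx)]), collapse = ", "),
           call. = FALSE)
    }
    return(idx)
  }
  idx <- as.integer(Z)
  if (any(idx < 1 | idx > n_ind)) stop("Z index out of range", call. = FALSE)
  idx
}

# eigendecompose G and build the reparameterization a = Q %*% gamma with
# gamma ~ N(0, I * sigma2_a) and Q' Z'Z Q diagonal (joint diagonalization of
# the additive prior and the record-count weighting)
.gibbs_basis <- function(G, counts, eg = NULL) {
  if (is.null(eg)) eg <- eigen(G, symmetric = TRUE)
  if (min(eg$values) <= 1e-8) {
    stop("G is not positive definite; apply grm_stabilize() first",
         call. = FALSE)
  }
  B <- sweep(eg$vectors, 2, sqrt(eg$values), `*`) # G = B B'
  A <- crossprod(B, counts * B)
  ea <- eigen(A, symmetric = TRUE)
  Q <- B %*% ea$vectors
  list(Q = Q, Qt = t(Q), lambda = pmax(ea$values, 0))
}

.id_sums <- function(x, idx, n_ind) {
  s <- numeric(n_ind)
  agg <- rowsum(x, group = idx)
  s[as.integer(rownames(agg))] <- agg
  s
}

.draw_var <- function(ss, n, prior) {
  df <- n + prior$nu
  (ss + prior$nu * prior$scale) / stats::rchisq(1, df)
}

.gibbs_uni <- function(y, X, id_index, G, config, use_pe, g_ids,
                       model_label, eg = NULL) {
  if (!inherits(config, "gibbs_config")) stop("config must be a gibbs_config")
  if (!is.null(config$seed)) set.seed(config$seed)
  N <- length(y)
  X <- as.matrix(X)
  stopifnot(nrow(X) == N, length(id_index) == N)
  n_ind <- nrow(G)
  counts <- tabulate(id_index, n_ind)
  if (use_pe && !any(counts >= 2)) {
    warning("all individuals have a single record: sigma2_pe and sigma2_e ",
            "are weakly identified", call. = FALSE)
  }
  basis <- .gibbs_basis(G, counts, eg)
  p <- ncol(X)
  R <- chol(crossprod(X))
  Xt <- t(X)
  prior <- config$prior

  vy <- stats::var(y)
  sigma2_e <- vy / 2
  sigma2_a <- vy / 4
  sigma2_pe <- if (use_pe) vy / 8 else 0
  b <- qr.coef(qr(X), y)
  gam <- numeric(n_ind)
  pe <- numeric(n_ind)
  a_rec <- numeric(N)
  pe_rec <- numeric(N)

  n_keep <- config$retained
  comp_names <- c("sigma2_a", if (use_pe) "sigma2_pe", "sigma2_e")
  samples <- matrix(NA_real_, n_keep, length(comp_names) + 2,
                    dimnames = list(NULL, c("iter", comp_names, "h2")))
  gam_draws <- matrix(NA_real_, n_ind, n_keep)
  b_draws <- matrix(NA_real_, p, n_keep, dimnames = list(colnames(X), NULL))
  rep_draws <- if (use_pe) numeric(n_keep) else NULL
  k <- 0L

  for (it in seq_len(config$iterations)) {
    # fixed effects (flat prior)
    rb <- y - a_rec - pe_rec
    bhat <- backsolve(R, forwardsolve(t(R), Xt %*% rb))
    b <- drop(bhat + backsolve(R, stats::rnorm(p)) * sqrt(sigma2_e))
    xb <- drop(X %*% b)

    # additive effects in the diagonalized basis
    r <- y - xb - pe_rec
    rhs <- drop(basis$Qt %*% .id_sums(r, id_index, n_ind)) / sigma2_e
    prec <- basis$lambda / sigma2_e + 1 / sigma2_a
    gam <- rhs / prec + stats::rnorm(n_ind) / sqrt(prec)
    a_ind <- drop(basis$Q %*% gam)
    a_rec <- a_ind[id_index]

    if (use_pe) {
      r2 <- y - xb - a_rec
      s2 <- .id_sums(r2, id_index, n_ind)
      prec_pe <- counts / sigma2_e + 1 / sigma2_pe
      pe <- (s2 / sigma2_e) / prec_pe + stats::rnorm(n_ind) / sqrt(prec_pe)
      pe_rec <- pe[id_index]
    }

    sigma2_a <- .draw_var(sum(gam^2), n_ind, prior)
    if (use_pe) sigma2_pe <- .draw_var(sum(pe^2), n_ind, prior)
    e <- y - xb - a_rec - pe_rec
    sigma2_e <- .draw_var(sum(e^2), N, prior)

    if (it > config$burn_in && (it - config$burn_in) %% config$thin == 0) {
      k <- k + 1L
      sp <- sigma2_a + sigma2_pe + sigma2_e
      row <- c(it, sigma2_a, if (use_pe) sigma2_pe, sigma2_e, sigma2_a / sp)
      samples[k, ] <- row
      if (use_pe) rep_draws[k] <- (sigma2_a + sigma2_pe) / sp
      gam_draws[, k] <- gam
      b_draws[, k] <- b
    }
  }

  samples <- tibble::as_tibble(samples)
  if (use_pe) samples$repeatability <- rep_draws
  a_draws <- basis$Q %*% gam_draws
  rownames(a_draws) <- g_ids
  gebv <- tibble::tibble(
    id = g_ids,
    gebv = rowMeans(a_draws),
    psd = apply(a_draws, 1, stats::sd)
  )
  structure(list(model = model_label, samples = samples, gebv = gebv,
                 a_draws = a_draws, b_draws = b_draws, config = config,
                 g_ids = g_ids, n_records = N, X = X, id_index = id_index),
            class = "reactigen_fit")
}

#' Single-trait linear animal model by Gibbs sampling
#'
#' Fits `y = X b + Z a + e` with `a ~ N(0, G sigma2_a)` and
#' `e ~ N(0, I sigma2_e)`, flat priors on `b` and (by default) on the
#' variances. Heritability is computed per retained draw as
#' `sigma2_a / (sigma2_a + sigma2_e)`. Internally the additive effects are
#' sampled in a basis that jointly diagonalizes the genomic covariance and
#' the record-incidence crossproduct, so every Gibbs update is a vector
#' operation.
#'
#' @param y Numeric response vector (one element per record).
#' @param X Fixed-effect design matrix (see [build_design()]).
#' @param Z Record-to-individual incidence: a 0/1 matrix with one 1 per row,
#'   an integer index into the GRM rows, or a character/factor vector of ids
#'   matching the GRM dimnames.
#' @param G A `"grm"` object (stabilized) or bare positive-definite matrix.
#'   When many fits share one GRM, store `eigen(G$G, symmetric = TRUE)` in
#'   the object's `eigen` field to skip the per-fit eigendecomposition.
#' @param config A [gibbs_config()].
#' @return A `"reactigen_fit"`: retained draws (`$samples`, a tibble with
#'   `sigma2_a`, `sigma2_e`, `h2`), posterior-mean GEBVs (`$gebv`), the full
#'   additive-effect draws (`$a_draws`, individuals x draws) and
#'   fixed-effect draws (`$b_draws`).
#' @export
gibbs_single_trait <- function(y, X, Z, G, config = gibbs_config()) {
  Gm <- .as_G(G)
  g_ids <- rownames(Gm)
  if (is.null(g_ids)) g_ids <- as.character(seq_len(nrow(Gm)))
  idx <- .as_id_index(Z, nrow(Gm), g_ids)
  .gibbs_uni(y, X, idx, Gm, config, use_pe = FALSE, g_ids, "single_trait",
             eg = if (inherits(G, "grm")) G$eigen else NULL)
}

#' Repeatability animal model by Gibbs sampling
#'
#' Fits `y = X b + Z a + W pe + e` with `a ~ N(0, G sigma2_a)`,
#' `pe ~ N(0, I sigma2_pe)` and `e ~ N(0, I sigma2_e)`. Heritability per draw
#' is `sigma2_a / (sigma2_a + sigma2_pe + sigma2_e)` and the repeatability
#' `(sigma2_a + sigma2_pe) / (sigma2_a + sigma2_pe + sigma2_e)` is reported
#' alongside. The permanent environmental effect is per individual, so `W`
#' must encode the same record-to-individual mapping as `Z` (pass `W = NULL`
#' to reuse `Z`).
#'
#' @inheritParams gibbs_single_trait
#' @param W Permanent-environment incidence; must match `Z`.
#' @return A `"reactigen_fit"` with additionally `sigma2_pe` and
#'   `repeatability` draw columns.
#' @export
gibbs_repeatability <- function(y, X, Z, W = NULL, G,
                                config = gibbs_config()) {
  Gm <- .as_G(G)
  g_ids <- rownames(Gm)
  if (is.null(g_ids)) g_ids <- as.character(seq_len(nrow(Gm)))
  idx <- .as_id_index(Z, nrow(Gm), g_ids)
  if (!is.null(W)) {
    idx_w <- .as_id_index(W, nrow(Gm), g_ids)
    if (!identical(idx, idx_w)) {
      stop("W must map records to the same individuals as Z ",
           "(permanent environment is per individual)", call. = FALSE)
    }
  }
  .gibbs_uni(y, X, idx, Gm, config, use_pe = TRUE, g_ids, "repeatability",
             eg = if (inherits(G, "grm")) G$eigen else NULL)
}

# inverse-Wishart draw: Sigma ~ IW(Psi, nu)
.riw <- function(Psi, nu) {
  W <- stats::rWishart(1, df = nu, Sigma = solve(Psi))[, , 1]
  solve(W)
}

#' Two-trait linear animal model by Gibbs sampling
#'
#' Joint fit of two single-record traits sharing the genomic covariance
#' kernel: additive effects `(a1, a2) ~ N(0, Sigma_a (x) G)` and residuals
#' i.i.d. `N(0, Sigma_e)` per individual. The genetic correlation is computed
#' per retained draw as `cov12 / sqrt(sigma2_a1 * sigma2_a2)` and the
#' phenotypic correlation from the summed component (co)variances.
#'
#' Individuals missing one trait are handled by data augmentation (the
#' missing record is drawn from its conditional each iteration); the residual
#' covariance is estimated from jointly recorded individuals and fixed at 0
#' when the record sets are disjoint. Convergence of the genetic-correlation
#' chain is assessed with the Geweke criterion and a failing fit is flagged
#' (`ftc = TRUE`) rather than silently summarized.
#'
#' @param y1,y2 Numeric vectors aligned with the GRM rows (one record per
#'   individual; `NA` = trait not recorded).
#' @param X1,X2 Fixed-effect design matrices (rows aligned with the GRM; must
#'   be complete even where the trait is missing).
#' @param G A stabilized `"grm"` or positive-definite matrix.
#' @param config A [gibbs_config()].
#' @param residual_covariance `"auto"` (default: estimate when at least 10
#'   individuals have both records, else fix at 0), `"estimate"`, or
#'   `"zero"`.
#' @return A `"reactigen_fit"` whose `$samples` has per-trait variance
#'   components and `h2`, plus `cov_a`, `rg` and `r_p`; `$gebv` and
#'   `$a_draws` are per-trait lists; `$ftc` flags Geweke failure of the `rg`
#'   chain.
#' @export
gibbs_two_trait <- function(y1, y2, X1, X2, G, config = gibbs_config(),
                            residual_covariance = c("auto", "estimate",
                                                    "zero")) {
  residual_covariance <- match.arg(residual_covariance)
  if (!is.null(config$seed)) set.seed(config$seed)
  Gm <- .as_G(G)
  n <- nrow(Gm)
  g_ids <- rownames(Gm)
  if (is.null(g_ids)) g_ids <- as.character(seq_len(n))
  X1 <- as.matrix(X1); X2 <- as.matrix(X2)
  stopifnot(length(y1) == n, length(y2) == n, nrow(X1) == n, nrow(X2) == n)
  obs1 <- !is.na(y1); obs2 <- !is.na(y2)
  if (any(!obs1 & !obs2)) {
    stop("individual(s) with no record for either trait: drop them from G",
         call. = FALSE)
  }
  if (sum(obs1) < 5 || sum(obs2) < 5) {
    stop("too few records to update the 2x2 covariance matrices",
         call. = FALSE)
  }
  overlap <- sum(obs1 & obs2)
  est_res_cov <- switch(residual_covariance,
                        estimate = TRUE, zero = FALSE,
                        auto = overlap >= 10)
  if (!est_res_cov && residual_covariance == "auto") {
    warning("fewer than 10 jointly recorded individuals: residual ",
            "covariance fixed at 0", call. = FALSE)
  }

  eg <- if (inherits(G, "grm") && !is.null(G$eigen)) G$eigen else
    eigen(Gm, symmetric = TRUE)
  if (min(eg$values) <= 1e-8) {
    stop("G is not positive definite; apply grm_stabilize() first",
         call. = FALSE)
  }
  U <- eg$vectors; d <- eg$values
  Ut <- t(U)
  Xt1 <- Ut %*% X1; Xt2 <- Ut %*% X2
  R1 <- chol(crossprod(X1)); R2 <- chol(crossprod(X2))
  any_miss <- any(!obs1) || any(!obs2)

  # initialize at a crude phenotypic-covariance split so chains do not have
  # to climb away from a zero genetic correlation
  y1c <- ifelse(obs1, y1, mean(y1[obs1]))
  y2c <- ifelse(obs2, y2, mean(y2[obs2]))
  Sy <- stats::cov(cbind(y1c, y2c))
  if (!est_res_cov) Sy[1, 2] <- Sy[2, 1] <- 0
  Sa <- Sy / 4 + diag(1e-4, 2)
  Se <- Sy / 2 + diag(1e-4, 2)
  b1 <- qr.coef(qr(X1), y1c); b2 <- qr.coef(qr(X2), y2c)
  al1 <- numeric(n); al2 <- numeric(n)
  yt1 <- drop(Ut %*% y1c); yt2 <- drop(Ut %*% y2c)

  prior <- config$prior
  nu_iw <- if (identical(prior$nu, -2)) -3 else prior$nu
  S0 <- diag(2) * prior$scale

  n_keep <- config$retained
  cols <- c("iter", "sigma2_a1", "sigma2_a2", "cov_a", "sigma2_e1",
            "sigma2_e2", "cov_e", "h2_1", "h2_2", "rg", "r_p")
  samples <- matrix(NA_real_, n_keep, length(cols),
                    dimnames = list(NULL, cols))
  al1_draws <- matrix(NA_real_, n, n_keep)
  al2_draws <- matrix(NA_real_, n, n_keep)
  k <- 0L

  for (it in seq_len(config$iterations)) {
    if (any_miss) {
      a1 <- drop(U %*% al1); a2 <- drop(U %*% al2)
      mu1 <- drop(X1 %*% b1) + a1
      mu2 <- drop(X2 %*% b2) + a2
      beta12 <- Se[1, 2] / Se[2, 2]
      beta21 <- Se[1, 2] / Se[1, 1]
      if (any(!obs1)) {
        i <- !obs1
        cond_mu <- mu1[i] + beta12 * (y2c[i] - mu2[i])
        cond_v <- Se[1, 1] - Se[1, 2]^2 / Se[2, 2]
        y1c[i] <- stats::rnorm(sum(i), cond_mu, sqrt(cond_v))
      }
      if (any(!obs2)) {
        i <- !obs2
        cond_mu <- mu2[i] + beta21 * (y1c[i] - mu1[i])
        cond_v <- Se[2, 2] - Se[1, 2]^2 / Se[1, 1]
        y2c[i] <- stats::rnorm(sum(i), cond_mu, sqrt(cond_v))
      }
      yt1 <- drop(Ut %*% y1c); yt2 <- drop(Ut %*% y2c)
    }

    # fixed effects, trait 1 given trait 2's residuals (conditional normal)
    e2 <- yt2 - drop(Xt2 %*% b2) - al2
    s11.2 <- Se[1, 1] - Se[1, 2]^2 / Se[2, 2]
    resp1 <- yt1 - al1 - (Se[1, 2] / Se[2, 2]) * e2
    bhat1 <- backsolve(R1, forwardsolve(t(R1), crossprod(Xt1, resp1)))
    b1 <- drop(bhat1 + backsolve(R1, stats::rnorm(ncol(X1))) * sqrt(s11.2))
    e1 <- yt1 - drop(Xt1 %*% b1) - al1
    s22.1 <- Se[2, 2] - Se[1, 2]^2 / Se[1, 1]
    resp2 <- yt2 - al2 - (Se[1, 2] / Se[1, 1]) * e1
    bhat2 <- backsolve(R2, forwardsolve(t(R2), crossprod(Xt2, resp2)))
    b2 <- drop(bhat2 + backsolve(R2, stats::rnorm(ncol(X2))) * sqrt(s22.1))

    # joint 2x2 update of the additive effects, vectorized over individuals
    Ei <- solve(Se); Ai <- solve(Sa)
    r1 <- yt1 - drop(Xt1 %*% b1)
    r2 <- yt2 - drop(Xt2 %*% b2)
    P11 <- Ei[1, 1] + Ai[1, 1] / d
    P12 <- Ei[1, 2] + Ai[1, 2] / d
    P22 <- Ei[2, 2] + Ai[2, 2] / d
    rhs1 <- Ei[1, 1] * r1 + Ei[1, 2] * r2
    rhs2 <- Ei[1, 2] * r1 + Ei[2, 2] * r2
    det <- P11 * P22 - P12^2
    C11 <- P22 / det; C22 <- P11 / det; C12 <- -P12 / det
    m1 <- C11 * rhs1 + C12 * rhs2
    m2 <- C12 * rhs1 + C22 * rhs2
    L11 <- sqrt(C11)
    L21 <- C12 / L11
    L22 <- sqrt(pmax(C22 - L21^2, 1e-12))
    z1 <- stats::rnorm(n); z2 <- stats::rnorm(n)
    al1 <- m1 + L11 * z1
    al2 <- m2 + L21 * z1 + L22 * z2

    # genetic covariance matrix
    Sgen <- matrix(c(sum(al1^2 / d), sum(al1 * al2 / d),
                     sum(al1 * al2 / d), sum(al2^2 / d)), 2, 2)
    Sa <- .riw(Sgen + S0, n + nu_iw)

    # residual covariance matrix
    ee1 <- r1 - al1; ee2 <- r2 - al2
    if (est_res_cov) {
      Sres <- matrix(c(sum(ee1^2), sum(ee1 * ee2),
                       sum(ee1 * ee2), sum(ee2^2)), 2, 2)
      Se <- .riw(Sres + S0, n + nu_iw)
    } else {
      Se <- diag(c(.draw_var(sum(ee1^2), n, prior),
                   .draw_var(sum(ee2^2), n, prior)))
    }

    if (it > config$burn_in && (it - config$burn_in) %% config$thin == 0) {
      k <- k + 1L
      sp1 <- Sa[1, 1] + Se[1, 1]; sp2 <- Sa[2, 2] + Se[2, 2]
      samples[k, ] <- c(
        it, Sa[1, 1], Sa[2, 2], Sa[1, 2], Se[1, 1], Se[2, 2], Se[1, 2],
        Sa[1, 1] / sp1, Sa[2, 2] / sp2,
        Sa[1, 2] / sqrt(Sa[1, 1] * Sa[2, 2]),
        (Sa[1, 2] + Se[1, 2]) / sqrt(sp1 * sp2))
      al1_draws[, k] <- al1
      al2_draws[, k] <- al2
    }
  }

  samples <- tibble::as_tibble(samples)
  a1_draws <- U %*% al1_draws; rownames(a1_draws) <- g_ids
  a2_draws <- U %*% al2_draws; rownames(a2_draws) <- g_ids
  gebv <- list(
    trait1 = tibble::tibble(id = g_ids, gebv = rowMeans(a1_draws),
                            psd = apply(a1_draws, 1, stats::sd)),
    trait2 = tibble::tibble(id = g_ids, gebv = rowMeans(a2_draws),
                            psd = apply(a2_draws, 1, stats::sd))
  )
  gw <- geweke(samples$rg)
  structure(list(model = "two_trait", samples = samples, gebv = gebv,
                 a_draws = list(trait1 = a1_draws, trait2 = a2_draws),
                 config = config, g_ids = g_ids,
                 n_records = c(sum(obs1), sum(obs2)),
                 X = list(trait1 = X1, trait2 = X2),
                 id_index = seq_len(n),
                 residual_cov_estimated = est_res_cov,
                 ftc = is.finite(gw$p) && gw$p < 0.05),
            class = "reactigen_fit")
}

#' Fit an animal model from a records table
#'
#' Data-frame-first wrapper around [gibbs_single_trait()] /
#' [gibbs_repeatability()]: builds the design from a [model_spec()]-style
#' description and dispatches on whether any individual has repeated records.
#'
#' @param records Data frame of phenotypic records.
#' @param response Trait column name.
#' @param grm A stabilized `"grm"`.
#' @param fixed,covariates Systematic effects (see [model_spec()]).
#' @param id Individual-id column (default `"sow_id"`).
#' @param repeated `NULL` (auto: repeatability model iff any id repeats) or
#'   logical.
#' @param config A [gibbs_config()].
#' @return A `"reactigen_fit"`.
#' @export
fit_animal_model <- function(records, response, grm,
                             fixed = character(0),
                             covariates = character(0), id = "sow_id",
                             repeated = NULL, config = gibbs_config()) {
  if (is.null(repeated)) repeated <- anyDuplicated(records[[id]]) > 0
  spec <- model_spec(response, fixed, covariates, id,
                     permanent_environment = repeated)
  g_ids <- rownames(.as_G(grm))
  des <- build_design(records, spec, g_ids)
  fit <- if (repeated) {
    gibbs_repeatability(des$y, des$X, des$id_index, NULL, grm, config)
  } else {
    gibbs_single_trait(des$y, des$X, des$id_index, grm, config)
  }
  fit$response <- response
  fit$spec <- spec
  fit
}
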
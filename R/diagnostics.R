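#' Geweke convergence diagnostic for a single chain
#'
#' Compares the means of an early and a late window of the chain with a
#' two-sample z-test whose variances are spectral-density estimates at
#' frequency zero, so autocorrelation within each window is accounted for.
#' The spectral variance uses a Bartlett-windowed autocovariance sum with a
#' lag cutoff of 4% of the window length.
#'
#' @param chain Numeric vector of at least 100 retained draws.
#' @param first_frac Fraction of the chain in the early window (default 0.1).
#' @param last_frac Fraction in the late window (default 0.5).
#' @return List with `z` and the two-sided normal `p`; a chain passes the
#'   criterion when `p > 0.05`.
#' @export
geweke <- function(chain, first_frac = 0.1, last_frac = 0.5) {
  n <- length(chain)
  stopifnot(n >= 100, first_frac > 0, last_frac > 0,
            first_frac + last_frac <= 1)
  if (stats::var(chain) == 0) {
    stop("degenerate chain: zero variance", call. = FALSE)
  }
  seg1 <- chain[seq_len(floor(first_frac * n))]
  seg2 <- chain[(n - floor(last_frac * n) + 1):n]
  z <- (mean(seg1) - mean(seg2)) /
    sqrt(.spectral_var0(seg1) / length(seg1) +
           .spectral_var0(seg2) / length(seg2))
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

# spectral density at frequency zero via Bartlett-weighted autocovariances
.spectral_var0 <- function(x) {
  n <- length(x)
  K <- max(1L, floor(0.04 * n))
  ac <- stats::acf(x, lag.max = K, type = "covariance", plot = FALSE,
                   demean = TRUE)$acf[, 1, 1]
  g0 <- ac[1]
  if (K >= 1 && length(ac) > 1) {
    w <- 1 - seq_len(length(ac) - 1) / (K + 1)
    s <- g0 + 2 * sum(w * ac[-1])
  } else {
    s <- g0
  }
  max(s, g0 * 1e-8)
}

#' Effective sample size of an MCMC chain
#'
#' `ESS = n / (1 + 2 * sum(rho_k))` with the autocorrelation sum truncated by
#' Geyer's initial positive sequence rule (pairs of successive
#' autocorrelations are accumulated while their sum stays positive). A chain
#' with negative lag-1 autocorrelation can legitimately return `ESS > n`.
#'
#' @param chain Numeric vector of at least 100 draws.
#' @return Positive effective sample size.
#' @export
effective_sample_size <- function(chain) {
  n <- length(chain)
  stopifnot(n >= 100)
  if (stats::var(chain) == 0) {
    stop("degenerate chain: zero variance", call. = FALSE)
  }
  lag_max <- min(n - 1, max(200L, floor(n / 2)))
  rho <- stats::acf(chain, lag.max = lag_max, plot = FALSE,
                    demean = TRUE)$acf[, 1, 1]
  # Geyer initial positive sequence on Gamma_m = rho(2m) + rho(2m+1)
  tau <- 0
  m <- 0
  repeat {
    i1 <- 2 * m + 1
    i2 <- 2 * m + 2
    if (i1 > length(rho)) break
    gam <- rho[i1] + if (i2 <= length(rho)) rho[i2] else 0
    if (gam <= 0) break
    tau <- tau + 2 * gam
    m <- m + 1
  }
  tau <- tau - 1 # Gamma_0 counts rho_0 = 1 twice
  n / max(tau, 1e-8)
}

#' Convergence diagnostics for the monitored components of a fit
#'
#' Geweke z/p and effective sample size for each retained-draw column of a
#' fitted model (or any table of chains).
#'
#' @param fit A `"reactigen_fit"` or a data frame of chains.
#' @param parameters Columns to assess (default: all non-`iter` columns).
#' @return Tibble with `parameter`, `geweke_z`, `geweke_p`, `ess`, `passed`
#'   (`geweke_p > 0.05`).
#' @export
chain_diagnostics <- function(fit, parameters = NULL) {
  samples <- if (inherits(fit, "reactigen_fit")) fit$samples else
    tibble::as_tibble(fit)
  if (is.null(parameters)) parameters <- setdiff(names(samples), "iter")
  purrr::map_dfr(parameters, function(par) {
    x <- samples[[par]]
    gw <- geweke(x)
    tibble::tibble(parameter = par, geweke_z = gw$z, geweke_p = gw$p,
                   ess = effective_sample_size(x), passed = gw$p > 0.05)
  })
}
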
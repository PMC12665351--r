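#' Heritability from variance components
#'
#' Plug-in heritability: `sigma2_a / (sigma2_a + sigma2_pe + sigma2_e)`. With
#' `sigma2_pe = 0` this is the single-record form; with a permanent
#' environmental variance it is the repeated-record form. In posterior
#' summaries heritability is computed per draw; this helper exists for
#' plug-in arithmetic on reported component means.
#'
#' @param sigma2_a Additive genetic variance.
#' @param sigma2_e Residual variance.
#' @param sigma2_pe Permanent environmental variance (default 0).
#' @return Numeric heritability in (0, 1).
#' @export
heritability <- function(sigma2_a, sigma2_e, sigma2_pe = 0) {
  sigma2_a / (sigma2_a + sigma2_pe + sigma2_e)
}

#' Posterior summary of a fitted animal model
#'
#' Posterior mean and posterior standard deviation (PSD) of every variance
#' component and derived quantity. Derived quantities (heritability, genetic
#' and phenotypic correlations, phenotypic variance) are computed per
#' retained draw and then summarized, never by plugging posterior means into
#' the formulas.
#'
#' @param fit A `"reactigen_fit"`.
#' @return Tibble with columns `component`, `mean`, `psd`.
#' @export
summarize_fit <- function(fit) {
  stopifnot(inherits(fit, "reactigen_fit"))
  draws <- fit$samples
  if (nrow(draws) < 100) {
    stop("need at least 100 retained draws to summarize", call. = FALSE)
  }
  draws <- dplyr::select(draws, -"iter")
  if (fit$model != "two_trait") {
    var_cols <- intersect(c("sigma2_a", "sigma2_pe", "sigma2_e"),
                          names(draws))
    draws$sigma2_p <- rowSums(draws[var_cols])
  } else {
    draws$sigma2_p1 <- draws$sigma2_a1 + draws$sigma2_e1
    draws$sigma2_p2 <- draws$sigma2_a2 + draws$sigma2_e2
  }
  out <- tibble::tibble(
    component = names(draws),
    mean = vapply(draws, mean, numeric(1)),
    psd = vapply(draws, stats::sd, numeric(1))
  )
  if (isTRUE(fit$ftc)) attr(out, "ftc") <- TRUE
  out
}

#' @export
print.reactigen_fit <- function(x, ...) {
  cat("<reactigen_fit> ", x$model,
      if (!is.null(x$response)) paste0(" for ", x$response),
      ": ", nrow(x$samples), " retained draws\n", sep = "")
  if (isTRUE(x$ftc)) cat("  ! flagged as failed to converge (FTC)\n")
  print(summarize_fit(x))
  invisible(x)
}

#' Tidy the posterior summary of a fitted animal model
#'
#' @param x A `"reactigen_fit"`.
#' @param ... Unused.
#' @return Tibble with `component`, `mean` (estimate) and `psd`.
#' @exportS3Method generics::tidy
tidy.reactigen_fit <- function(x, ...) summarize_fit(x)

#' One-row summary of a fitted animal model
#'
#' @param x A `"reactigen_fit"`.
#' @param ... Unused.
#' @return One-row tibble: model type, chain settings, retained draws,
#'   posterior mean heritability, minimum effective sample size across
#'   variance components, and the convergence flag.
#' @exportS3Method generics::glance
glance.reactigen_fit <- function(x, ...) {
  diag <- chain_diagnostics(x)
  h2_col <- intersect(c("h2", "h2_1"), names(x$samples))[1]
  tibble::tibble(
    model = x$model,
    iterations = x$config$iterations,
    burn_in = x$config$burn_in,
    thin = x$config$thin,
    retained = nrow(x$samples),
    h2 = mean(x$samples[[h2_col]]),
    min_ess = min(diag$ess),
    converged = all(diag$passed) && !isTRUE(x$ftc)
  )
}

#' Trace and density plots for a fitted animal model
#'
#' @param object A `"reactigen_fit"`.
#' @param parameters Columns of `object$samples` to display (default: all
#'   variance components and derived quantities).
#' @param ... Unused.
#' @return A ggplot object: one trace panel per parameter.
#' @exportS3Method ggplot2::autoplot
autoplot.reactigen_fit <- function(object, parameters = NULL, ...) {
  samples <- object$samples
  if (is.null(parameters)) parameters <- setdiff(names(samples), "iter")
  long <- tidyr::pivot_longer(samples[c("iter", parameters)],
                              -"iter", names_to = "parameter")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$iter, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = "Iteration", y = "Sampled value") +
    ggplot2::theme_minimal()
}
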
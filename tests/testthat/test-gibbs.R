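test_that("gibbs_config enforces the chain arithmetic invariants", {
  cfg <- gibbs_config(1600, 500, 10)
  expect_equal(cfg$retained, floor((1600 - 500) / 10))
  expect_error(gibbs_config(1000, 1000, 10), "burn_in")
  expect_error(gibbs_config(1000, 500, 10), "at least 100")
})

test_that("the single-trait sampler is reproducible and respects bounds", {
  set.seed(20)
  g <- simulate_genotypes(60, 300, maf_range = c(0.1, 0.5), seed = 20)
  G <- grm_stabilize(grm_vanraden(g), 0.01)
  sim <- simulate_phenotypes(g, h2 = c(y = 0.3), n_groups = 1, seed = 21)
  y <- sim$phenotypes$y
  X <- matrix(1, 60, 1)
  f1 <- gibbs_single_trait(y, X, seq_len(60), G, test_config())
  f2 <- gibbs_single_trait(y, X, seq_len(60), G, test_config())
  expect_equal(f1$samples, f2$samples)
  expect_equal(nrow(f1$samples), test_config()$retained)
  expect_true(all(f1$samples$sigma2_a > 0))
  expect_true(all(f1$samples$sigma2_e > 0))
  expect_true(all(f1$samples$h2 > 0 & f1$samples$h2 < 1))
  expect_equal(nrow(f1$gebv), 60)
  # non-positive-definite kernel is rejected with advice
  raw <- grm_vanraden(make_geno(matrix(c(0, 1, 2), 3, 1)))
  expect_error(
    gibbs_single_trait(c(1, 2, 3), matrix(1, 3, 1), 1:3, raw, test_config()),
    "stabilize")
})

test_that("a trait without additive signal concentrates h2 near zero", {
  set.seed(22)
  g <- simulate_genotypes(400, 800, maf_range = c(0.05, 0.5), seed = 22)
  G <- grm_stabilize(grm_vanraden(g), 0.01)
  y <- rnorm(400)
  fit <- gibbs_single_trait(y, matrix(1, 400, 1), seq_len(400), G,
                            gibbs_config(2000, 500, 3, seed = 23))
  expect_lt(mean(fit$samples$h2), 0.10)
})

test_that("the repeatability model recovers pe and warns when unidentified", {
  set.seed(24)
  g <- simulate_genotypes(250, 600, maf_range = c(0.05, 0.5), seed = 24)
  G <- grm_stabilize(grm_vanraden(g), 0.01)
  sim <- simulate_phenotypes(g, h2 = c(y = 0.12), pe_fraction = c(y = 0.25),
                             n_records = 3, n_groups = 4, seed = 25)
  fit <- fit_animal_model(sim$phenotypes, "y", G, fixed = "group",
                          config = gibbs_config(2500, 600, 3, seed = 26))
  expect_equal(fit$model, "repeatability")
  sm <- summarize_fit(fit)
  expect_lt(abs(sm$mean[sm$component == "h2"] - 0.12), 0.15)
  expect_lt(abs(sm$mean[sm$component == "sigma2_pe"] - 0.25), 0.15)
  expect_true(all(fit$samples$repeatability > fit$samples$h2))

  single <- sim$phenotypes[sim$phenotypes$record == 1, ]
  expect_warning(
    gibbs_repeatability(single$y, matrix(1, 250, 1), seq_len(250), NULL, G,
                        test_config()),
    "weakly identified")
})

test_that("two-trait fits bound rg and recognize self-correlation", {
  set.seed(27)
  g <- simulate_genotypes(150, 500, maf_range = c(0.1, 0.5), seed = 27)
  G <- grm_stabilize(grm_vanraden(g), 0.01)
  sim <- simulate_phenotypes(g, h2 = c(t1 = 0.3), n_groups = 1, seed = 28)
  y <- sim$phenotypes$t1
  X <- matrix(1, 150, 1)
  fit <- gibbs_two_trait(y, y, X, X, G, test_config())
  expect_gt(mean(fit$samples$rg), 0.98)
  expect_true(all(abs(fit$samples$rg) <= 1))
  expect_true(all(fit$samples$h2_1 > 0 & fit$samples$h2_1 < 1))
})

test_that("independent traits give a genetic correlation near zero", {
  set.seed(29)
  g <- simulate_genotypes(300, 700, maf_range = c(0.05, 0.5), seed = 29)
  G <- grm_stabilize(grm_vanraden(g), 0.01)
  sim <- simulate_phenotypes(g, h2 = c(t1 = 0.35, t2 = 0.35), rg = diag(2),
                             n_groups = 1, seed = 30)
  X <- matrix(1, 300, 1)
  fit <- gibbs_two_trait(sim$phenotypes$t1, sim$phenotypes$t2, X, X, G,
                         gibbs_config(3000, 800, 4, seed = 31))
  expect_lt(abs(mean(fit$samples$rg)), 0.3)
})

test_that("two-trait fits augment individuals missing one record", {
  set.seed(32)
  g <- simulate_genotypes(200, 500, maf_range = c(0.1, 0.5), seed = 32)
  G <- grm_stabilize(grm_vanraden(g), 0.01)
  sim <- simulate_phenotypes(g, h2 = c(t1 = 0.3, t2 = 0.3),
                             rg = matrix(c(1, .7, .7, 1), 2),
                             n_groups = 1, seed = 33)
  y1 <- sim$phenotypes$t1; y2 <- sim$phenotypes$t2
  y2[1:40] <- NA
  X <- matrix(1, 200, 1)
  fit <- gibbs_two_trait(y1, y2, X, X, G, test_config())
  expect_equal(fit$n_records, c(200L, 160L), ignore_attr = TRUE)
  expect_true(all(is.finite(fit$samples$rg)))
  # disjoint record sets force the residual covariance to zero
  y1d <- y1; y1d[101:200] <- NA
  y2d <- y2; y2d[1:100] <- NA; y2d[101:200] <- sim$phenotypes$t2[101:200]
  expect_warning(
    fitd <- gibbs_two_trait(y1d, y2d, X, X, G, test_config()),
    "residual")
  expect_true(all(fitd$samples$cov_e == 0))
})

test_that("summaries, tidiers and diagnostics expose the fit", {
  set.seed(34)
  g <- simulate_genotypes(80, 300, maf_range = c(0.1, 0.5), seed = 34)
  G <- grm_stabilize(grm_vanraden(g), 0.01)
  sim <- simulate_phenotypes(g, h2 = c(y = 0.3), n_groups = 3, seed = 35)
  fit <- fit_animal_model(sim$phenotypes, "y", G, fixed = "group",
                          config = test_config())
  sm <- summarize_fit(fit)
  expect_true(all(c("sigma2_a", "sigma2_e", "h2", "sigma2_p") %in%
                    sm$component))
  # derived rows are per-draw summaries, not plug-in arithmetic
  h2_mean <- mean(fit$samples$sigma2_a /
                    (fit$samples$sigma2_a + fit$samples$sigma2_e))
  expect_equal(sm$mean[sm$component == "h2"], h2_mean, ignore_attr = TRUE)
  expect_equal(tidy(fit), sm)
  gl <- glance(fit)
  expect_equal(gl$retained, nrow(fit$samples))
  expect_s3_class(autoplot(fit), "ggplot")
})
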
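test_that("Me thresholds match the closed form and are monotone in L", {
  map1 <- tibble::tibble(marker = c("a", "b"), chrom = "chr1",
                         pos = c(1, 1e8 + 1))     # span 1e8 bp = 1 Morgan
  thr <- me_thresholds(map1, Ne = 100, alpha = 0.05, cm_per_mb = 1)
  expect_equal(thr$L_morgan, 1)
  expect_equal(thr$Me, 200 / log(100), tolerance = 1e-10)
  expect_equal(thr$threshold, 0.05 / (200 / log(100)), tolerance = 1e-10)

  # threshold strictly decreases as chromosome length grows
  Ls <- seq(0.5, 3, by = 0.1)
  thrs <- vapply(Ls, function(L) {
    map <- tibble::tibble(marker = c("a", "b"), chrom = "c",
                          pos = c(1, L * 1e8 + 1))
    me_thresholds(map)$threshold
  }, numeric(1))
  expect_true(all(diff(thrs) < 0))

  # switching the log base rescales Me
  thr10 <- me_thresholds(map1, log_base = 10)
  expect_equal(thr10$Me, 200 / log10(100), tolerance = 1e-10)

  expect_error(me_thresholds(tibble::tibble(marker = "a", chrom = "c",
                                            pos = 5)), "span")
  tiny <- tibble::tibble(marker = c("a", "b"), chrom = "c", pos = c(1, 500))
  expect_error(me_thresholds(tiny), "log")
})

test_that("genomic inflation matches its reference points", {
  expect_equal(genomic_inflation(rep(0.5, 200)), 1)
  set.seed(50)
  u <- runif(10000)
  expect_lt(abs(genomic_inflation(u) - 1), 0.03)
  # doubling every chi-square statistic doubles lambda
  p_infl <- pchisq(2 * qchisq(u, 1, lower.tail = FALSE), 1,
                   lower.tail = FALSE)
  expect_lt(abs(genomic_inflation(p_infl) - 2), 0.1)
  expect_error(genomic_inflation(c(rep(0.5, 100), 0)), "0, 1")
  expect_error(genomic_inflation(rep(0.5, 50)), "100")
})

test_that("variance explained follows 2p(1-p)e^2 / total", {
  expect_equal(variance_explained(0, 0.3, 2), 0)
  # full-variance edge: 2p(1-p) e^2 equals the phenotypic variance
  e <- sqrt(4 / 0.5)
  expect_equal(variance_explained(e, 0.5, 4), 1)
  expect_error(variance_explained(1, 0, 2), "monomorphic")
})

test_that("candidate windows flank, clamp and merge", {
  res <- tibble::tibble(
    chrom = c("SSC10", "chr2", "chr3", "chr3"),
    pos = c(54710198, 50000, 5e6, 5e6 + 120000),
    significant = TRUE)
  win <- candidate_windows(res, flank_bp = 1e5)
  ssc10 <- win[win$chrom == "SSC10", ]
  expect_equal(ssc10$start, 54610198)
  expect_equal(ssc10$end, 54810198)
  expect_equal(win$start[win$chrom == "chr2"], 0)
  merged <- win[win$chrom == "chr3", ]
  expect_equal(nrow(merged), 1)
  expect_equal(merged$n_markers, 2L)
  expect_equal(merged$end - merged$start, 120000 + 2e5)

  none <- candidate_windows(dplyr::mutate(res, significant = FALSE))
  expect_equal(nrow(none), 0)

  path <- withr::local_tempfile(fileext = ".bed")
  write_bed(win, path)
  bed <- read.table(path)
  expect_equal(nrow(bed), nrow(win))
})

test_that("back-solving is linear and invariant to marker order", {
  set.seed(51)
  g <- simulate_genotypes(80, 200, maf_range = c(0.1, 0.5), seed = 51)
  grm <- grm_stabilize(grm_vanraden(g), 0.01)
  a_draws <- matrix(rnorm(80 * 120), 80, 120,
                    dimnames = list(rownames(grm$G), NULL))
  X <- matrix(1, 80, 1)
  args <- list(fit = NULL, geno = g, grm = grm, sigma2_a = 0.5,
               sigma2_e = 0.5, sigma2_pe = 0, X = X, id_index = 1:80)
  eff <- do.call(backsolve_snp_effects, c(args, list(a_draws = a_draws)))
  # zero GEBVs give zero effects; doubling GEBVs doubles effects
  eff0 <- do.call(backsolve_snp_effects,
                  c(args, list(a_draws = a_draws * 0)))
  expect_true(all(eff0$effect == 0))
  eff2 <- do.call(backsolve_snp_effects,
                  c(args, list(a_draws = a_draws * 2)))
  expect_equal(eff2$effect, 2 * eff$effect)

  # permuting markers permutes the effects
  perm <- sample(200)
  gp <- genotypes(g$dosages[, perm], g$map[perm, ])
  effp <- do.call(backsolve_snp_effects,
                  c(list(fit = NULL, geno = gp, grm = grm,
                         sigma2_a = 0.5, sigma2_e = 0.5, sigma2_pe = 0,
                         X = X, id_index = 1:80),
                    list(a_draws = a_draws)))
  expect_equal(effp$effect, eff$effect[perm])
})

test_that("approximate p-values follow the normal tail of z", {
  eff <- tibble::tibble(effect = c(0, 3, 1), effect_se = c(1, 1, 0))
  pv <- approx_pvalues(eff)
  expect_equal(pv$p_value[1], 1)
  expect_equal(pv$p_value[2], 2 * pnorm(-3))
  expect_equal(pv$p_value[3], 1)
  expect_true(pv$unidentified[3])
})

test_that("a large planted QTL is the top association signal", {
  set.seed(52)
  g <- simulate_genotypes(400, 1000, maf_range = c(0.1, 0.5), seed = 52)
  G <- grm_stabilize(grm_vanraden(g), 0.01)
  sim <- simulate_phenotypes(
    g, h2 = c(y = 0.4),
    planted_qtl = list(y = data.frame(marker = 500, var_frac = 0.15)),
    n_groups = 1, seed = 53)
  fit <- gibbs_single_trait(sim$phenotypes$y, matrix(1, 400, 1),
                            seq_len(400), G,
                            gibbs_config(2000, 500, 3, seed = 54))
  gw <- run_gwas(fit, g, G)
  expect_s3_class(gw, "reactigen_gwas")
  expect_equal(unname(which.min(gw$p_value)), 500L)
  expect_equal(unname(which.max(abs(gw$effect))), 500L)
  expect_equal(unname(which.max(gw$variance_explained)), 500L)
  expect_true(all(gw$p_value > 0 & gw$p_value <= 1))
  expect_true(is.numeric(attr(gw, "lambda")))
  expect_s3_class(autoplot(gw), "ggplot")
})
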
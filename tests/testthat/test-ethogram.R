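test_that("posture-change scores are the signed ordinal level differences", {
  expect_identical(posture_change_score("LDS", "STD"), 2L)
  expect_identical(posture_change_score("STD", "LDS"), -2L)
  expect_identical(posture_change_score("SIT", "SIT"), 0L)
  expect_identical(posture_change_score("LDL", "STD"), 3L)
  expect_identical(posture_change_score("STD", "LDL"), -3L)
  expect_error(posture_change_score("LDS", "XYZ"), "XYZ")
})

test_that("posture-change scoring is antisymmetric over all 16 ordered pairs", {
  codes <- names(posture_levels)
  pairs <- expand.grid(a = codes, b = codes, stringsAsFactors = FALSE)
  # brute-force oracle: difference of the ordinal levels
  oracle <- posture_levels[pairs$b] - posture_levels[pairs$a]
  got <- posture_change_score(pairs$a, pairs$b)
  expect_identical(got, unname(oracle))
  expect_identical(got, -posture_change_score(pairs$b, pairs$a))
  expect_true(all(got >= -3 & got <= 3))
})

test_that("stage vocalization lookup is the exact 8-subset bijection", {
  subsets <- list(character(0), "SGT", c("SGT", "LGT"), "LGT",
                  c("SGT", "LGT", "BRK"), c("SGT", "BRK"),
                  c("LGT", "BRK"), "BRK")
  scores <- vocalization_stage_score(subsets)
  expect_identical(scores, 0:7)
  # bijection: enumerating every subset in arbitrary element order hits each
  # score exactly once
  shuffled <- lapply(subsets, rev)
  expect_setequal(vocalization_stage_score(shuffled), 0:7)
})

test_that("VS sums stage scores and validates the stage count", {
  expect_identical(vocalization_score(list("SGT", "SGT", "SGT")), 3L)
  expect_identical(
    vocalization_score(list(character(0), character(0), character(0),
                            character(0))), 0L)
  expect_identical(
    vocalization_score(list("BRK", "BRK", c("SGT", "LGT", "BRK"),
                            c("SGT", "LGT"))), 20L)
  expect_error(vocalization_score(list("SGT", "SGT")), "3 or 4")
  expect_error(vocalization_score(rep(list("SGT"), 5)), "3 or 4")
  # stage order invariance
  stages <- list("BRK", c("SGT", "LGT"), "NONE", "LGT")
  expect_identical(vocalization_score(stages),
                   vocalization_score(rev(stages)))
})

test_that("RS combines VS and posture changes additively and monotonically", {
  expect_identical(responsiveness_score(0L, c(0, 0)), 0L)
  expect_identical(responsiveness_score(4L, c(1, 1)), 6L)
  expect_identical(responsiveness_score(3L, c(-2, -1)), 0L)
  # raising one stage's score (adding a bark to a silent stage) raises RS
  base_stages <- list("SGT", "NONE", "SGT")
  louder <- list("SGT", "BRK", "SGT")
  pc <- c(1, 1)
  expect_gt(responsiveness_score(vocalization_score(louder), pc),
            responsiveness_score(vocalization_score(base_stages), pc))
})

test_that("score_sessions derives traits, drops incomplete records and trims ST", {
  set.seed(7)
  n <- 100
  sess <- dplyr::bind_rows(lapply(seq_len(n), function(i) {
    make_session(sow_id = sprintf("s%03d", i),
                 st = exp(rnorm(1, log(50), 0.2)))
  }))
  # push one shave time far beyond 3 SD of the sample
  sess$shave_time_s[5] <- mean(sess$shave_time_s) +
    5 * sd(sess$shave_time_s) * 10
  scored <- score_sessions(sess)
  expect_equal(nrow(scored), n - 1)
  expect_false("s005" %in% scored$sow_id)
  expect_equal(unname(attr(scored, "dropped")["st_outlier"]), 1)
  # traits recompute from the raw pieces
  expect_equal(scored$rs,
               scored$vs + scored$posture_change_1 + scored$posture_change_2)
  expect_true(all(scored$n_voc_stages %in% 3:4))
  # covariates carried through
  expect_true(all(c("touches", "intervention_moment", "contemporary_group")
                  %in% names(scored)))
})

test_that("degenerate session tables are handled explicitly", {
  one <- score_sessions(make_session())
  expect_equal(nrow(one), 1)
  expect_true(is.na(trait_summary(one)$sd[1]))

  sess <- dplyr::bind_rows(make_session("a"), make_session("b"))
  sess$posture_2[2] <- NA
  expect_message(scored <- score_sessions(sess), "dropped")
  expect_equal(scored$sow_id, "a")

  expect_warning(empty <- score_sessions(make_session()[0, ]), "no sessions")
  expect_equal(nrow(empty), 0)
})

test_that("trait summaries report CV = SD/mean", {
  x <- tibble::tibble(rs = c(2, 4, 6, 8), vs = c(1, 1, 1, 1),
                      st = c(30, 50, 70, 90))
  ts <- trait_summary(x)
  expect_equal(ts$cv[ts$trait == "rs"], sd(x$rs) / mean(x$rs))
  expect_equal(ts$mean[ts$trait == "st"], 60)
  expect_equal(cv(3.35, 5.74), 3.35 / 5.74)
})

test_that("sessions round-trip through CSV", {
  sess <- dplyr::bind_rows(
    make_session("a", vocs = c("NONE", "SGT+LGT", NA, "BRK")),
    make_session("b", vocs = c("SGT", "NONE", "LGT+BRK", "SGT"),
                 intervention = "before_first_site"))
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(sess, path, na = "")
  back <- read_sessions(path)
  expect_equal(score_sessions(back)$vs, score_sessions(sess)$vs)
})
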
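#' Posture codes of the handling-test ethogram
#'
#' The four postures recorded during a shaving session, ordered from least
#' alert (lying laterally) to most alert (standing). The integer level of each
#' code is the ordinal position used by [posture_change_score()].
#'
#' @format Named integer vector: `LDL = 0`, `LDS = 1`, `SIT = 2`, `STD = 3`.
#' @export
posture_levels <- c(LDL = 0L, LDS = 1L, SIT = 2L, STD = 3L)

#' Vocalization types of the handling-test ethogram
#'
#' Short grunt (SGT), long grunt (LGT) and bark (BRK), in increasing order of
#' alertness. A stage observation is any subset of these (empty = silent).
#'
#' @format Character vector of the three type abbreviations.
#' @export
vocal_types <- c("SGT", "LGT", "BRK")

# stage-score lookup: subset of {SGT, LGT, BRK} -> score 0..7, keyed by the
# canonical "SGT+LGT+BRK" ordering
.voc_score_table <- c(
  " "           = 0L,
  "SGT"         = 1L,
  "SGT+LGT"     = 2L,
  "LGT"         = 3L,
  "SGT+LGT+BRK" = 4L,
  "SGT+BRK"     = 5L,
  "LGT+BRK"     = 6L,
  "BRK"         = 7L
)

.voc_key <- function(observed) {
  observed <- unique(observed[!is.na(observed) & observed != "" &
                                observed != "NONE"])
  bad <- setdiff(observed, vocal_types)
  if (length(bad) > 0) {
    stop("unknown vocalization type(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  key <- paste(vocal_types[vocal_types %in% observed], collapse = "+")
  if (key == "") " " else key
}

#' Score a postural change between two observation time points
#'
#' Postures are ordinal levels from least alert (`LDL`) to most alert (`STD`);
#' the score is the signed difference in levels, so it ranges over -3..3 and a
#' positive value means the sow became more alert.
#'
#' @param prev,curr Character vectors of posture codes (`"LDL"`, `"LDS"`,
#'   `"SIT"`, `"STD"`). Recycled to a common length.
#' @return Integer vector of signed change scores in `[-3, 3]`.
#' @examples
#' posture_change_score("LDS", "STD") # 2
#' posture_change_score("STD", "LDS") # -2
#' @export
posture_change_score <- function(prev, curr) {
  lev_prev <- posture_levels[as.character(prev)]
  lev_curr <- posture_levels[as.character(curr)]
  bad <- unique(c(as.character(prev)[is.na(lev_prev)],
                  as.character(curr)[is.na(lev_curr)]))
  bad <- bad[!is.na(bad)]
  if (length(bad) > 0) {
    stop("unknown posture code(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(prev) || anyNA(curr)) {
    stop("missing posture observation", call. = FALSE)
  }
  unname(lev_curr - lev_prev)
}

#' Score the vocalization types heard during one stage of the handling test
#'
#' Exact lookup of the 8 possible subsets of {SGT, LGT, BRK} onto the 0-7
#' alertness scale: silence scores 0, a lone bark scores 7.
#'
#' @param observed Character vector of types heard in one stage (a subset of
#'   [vocal_types]; empty vector, `""`, `"NONE"` or `NA` mean silence), or a
#'   list of such vectors for several stages.
#' @return Integer score(s) in `[0, 7]`.
#' @examples
#' vocalization_stage_score(character(0)) # 0
#' vocalization_stage_score(c("SGT", "LGT", "BRK")) # 4
#' vocalization_stage_score("BRK") # 7
#' @export
vocalization_stage_score <- function(observed) {
  if (!is.list(observed)) observed <- list(observed)
  vapply(observed, function(x) .voc_score_table[[.voc_key(x)]], integer(1))
}

#' Total vocalization score (VS) across the stages of a session
#'
#' Each of the 3 or 4 stages of the shaving process is scored with
#' [vocalization_stage_score()] and the stage scores are summed. Sessions
#' without a repositioning intervention have 3 stages; intervened sessions
#' have 4.
#'
#' @param stage_vocalizations List of 3 or 4 stage observations, each a
#'   character vector subset of [vocal_types].
#' @return Integer VS in `[0, 7 * n_stages]`.
#' @examples
#' vocalization_score(list("SGT", "SGT", "SGT")) # 3
#' @export
vocalization_score <- function(stage_vocalizations) {
  if (!is.list(stage_vocalizations)) {
    stop("`stage_vocalizations` must be a list of per-stage subsets",
         call. = FALSE)
  }
  n <- length(stage_vocalizations)
  if (n < 3 || n > 4) {
    stop("malformed session: expected 3 or 4 vocalization stages, got ", n,
         call. = FALSE)
  }
  sum(vocalization_stage_score(stage_vocalizations))
}

#' Responsiveness score (RS) combining vocalization and postural change
#'
#' RS adds the session's vocalization score to the two signed posture-change
#' scores, so increased alertness (standing up, barking) raises RS and a
#' silent sow that never moves scores 0.
#'
#' @param vs Non-negative integer vocalization score.
#' @param posture_change_scores Numeric vector of the two signed
#'   posture-change scores, or a matrix/data frame with two columns when `vs`
#'   is a vector.
#' @return Integer RS (may be negative if alertness decreased).
#' @export
responsiveness_score <- function(vs, posture_change_scores) {
  if (is.data.frame(posture_change_scores)) {
    posture_change_scores <- as.matrix(posture_change_scores)
  }
  if (is.matrix(posture_change_scores)) {
    stopifnot(ncol(posture_change_scores) == 2,
              nrow(posture_change_scores) == length(vs))
    return(as.integer(vs + rowSums(posture_change_scores)))
  }
  stopifnot(length(posture_change_scores) == 2, length(vs) == 1)
  as.integer(vs + sum(posture_change_scores))
}

#' Score a table of ethogram sessions into behavioral traits
#'
#' Derives the three behavioral traits from raw session records: RS
#' (responsiveness), VS (vocalization) and ST (shave time, seconds). Sessions
#' with a missing posture observation are dropped with a message. Records of
#' the continuous trait ST lying more than `outlier_sd` standard deviations
#' from its mean are removed; the categorical scores are never trimmed.
#'
#' @param sessions Data frame with one row per sow-session and columns
#'   `sow_id`, `posture_1`..`posture_3` (codes in [posture_levels]),
#'   `voc_1`..`voc_4` (`"+"`- or `";"`-separated type lists; `voc_4` is `NA`
#'   for 3-stage sessions), `shave_time_s`, and any covariate columns (e.g.
#'   `touches`, `intervention_moment`, `hair_density`, `contemporary_group`),
#'   which are carried through.
#' @param outlier_sd Multiple of the standard deviation beyond which ST
#'   records are discarded (default 3); `Inf` disables trimming. No trimming
#'   is attempted when fewer than 2 sessions remain (SD undefined).
#' @return Tibble with one row per retained session: `sow_id`, the traits
#'   `rs`, `vs`, `st`, the two signed `posture_change_*` scores, the number of
#'   vocalization stages, and the carried covariates. The number of sessions
#'   dropped at each step is recorded in the `"dropped"` attribute.
#' @export
score_sessions <- function(sessions, outlier_sd = 3) {
  if (nrow(sessions) == 0) {
    warning("no sessions supplied; returning empty score table",
            call. = FALSE)
    return(tibble::tibble(sow_id = character(0), rs = integer(0),
                          vs = integer(0), st = numeric(0)))
  }
  need <- c("sow_id", "posture_1", "posture_2", "posture_3", "shave_time_s")
  missing_cols <- setdiff(need, names(sessions))
  if (length(missing_cols) > 0) {
    stop("sessions table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  sessions <- tibble::as_tibble(sessions)

  complete_posture <- !is.na(sessions$posture_1) &
    !is.na(sessions$posture_2) & !is.na(sessions$posture_3) &
    !is.na(sessions$shave_time_s)
  n_dropped_incomplete <- sum(!complete_posture)
  if (n_dropped_incomplete > 0) {
    message(n_dropped_incomplete,
            " session(s) dropped: incomplete posture or shave-time record")
  }
  kept <- sessions[complete_posture, , drop = FALSE]
  if (any(kept$shave_time_s <= 0)) {
    stop("shave_time_s must be positive", call. = FALSE)
  }

  voc_cols <- intersect(paste0("voc_", 1:4), names(kept))
  split_voc <- function(x) {
    if (is.na(x)) return(NA)
    trimws(strsplit(as.character(x), "[;+]")[[1]])
  }
  stage_lists <- purrr::pmap(kept[voc_cols], function(...) {
    stages <- purrr::map(list(...), split_voc)
    stages[!vapply(stages, function(s) length(s) == 1 && all(is.na(s)),
                   logical(1))]
  })

  pc1 <- posture_change_score(kept$posture_1, kept$posture_2)
  pc2 <- posture_change_score(kept$posture_2, kept$posture_3)
  vs <- vapply(stage_lists, vocalization_score, numeric(1))
  scored <- dplyr::bind_cols(
    tibble::tibble(
      sow_id = kept$sow_id,
      rs = as.integer(vs + pc1 + pc2),
      vs = as.integer(vs),
      st = as.numeric(kept$shave_time_s),
      posture_change_1 = pc1,
      posture_change_2 = pc2,
      n_voc_stages = lengths(stage_lists)
    ),
    kept[setdiff(names(kept),
                 c(need, voc_cols))]
  )

  # 3-SD trimming applies to the continuous trait only
  n_outliers <- 0L
  if (is.finite(outlier_sd) && nrow(scored) >= 2) {
    st_sd <- stats::sd(scored$st)
    if (isTRUE(st_sd > 0)) {
      keep_st <- abs(scored$st - mean(scored$st)) <= outlier_sd * st_sd
      n_outliers <- sum(!keep_st)
      scored <- scored[keep_st, , drop = FALSE]
    }
  }
  attr(scored, "dropped") <- c(incomplete = n_dropped_incomplete,
                               st_outlier = n_outliers)
  scored
}

#' Coefficient of variation
#'
#' `cv = sd / mean`, the scale-free dispersion measure reported alongside the
#' trait summaries.
#'
#' @param sd,mean Standard deviation and mean (vectorized).
#' @return Numeric CV (fraction, not percent).
#' @export
cv <- function(sd, mean) sd / mean

#' Descriptive statistics for the behavioral traits
#'
#' Min, median, mean, max, SD and coefficient of variation (SD/mean) for each
#' requested trait column of a scored-session table.
#'
#' @param scored Tibble from [score_sessions()] (or any table with numeric
#'   trait columns).
#' @param traits Character vector of trait column names (default
#'   `c("rs", "vs", "st")`, intersected with available columns).
#' @return Tibble with one row per trait: `trait`, `n`, `min`, `median`,
#'   `mean`, `max`, `sd`, `cv`. With a single record SD and CV are `NA`.
#' @export
trait_summary <- function(scored, traits = c("rs", "vs", "st")) {
  traits <- intersect(traits, names(scored))
  purrr::map_dfr(traits, function(tr) {
    x <- scored[[tr]]
    x <- x[!is.na(x)]
    s <- if (length(x) >= 2) stats::sd(x) else NA_real_
    m <- mean(x)
    tibble::tibble(
      trait = tr, n = length(x),
      min = min(x), median = stats::median(x), mean = m, max = max(x),
      sd = s, cv = cv(s, m)
    )
  })
}

#' Read ethogram sessions from a delimited text file
#'
#' @param path CSV file with the columns described in [score_sessions()].
#'   A six-row example ships with the package:
#'   `system.file("extdata", "example_sessions.csv", package = "reactigen")`.
#' @return Tibble of sessions.
#' @examples
#' sessions <- read_sessions(system.file("extdata", "example_sessions.csv",
#'                                       package = "reactigen"))
#' score_sessions(sessions)
#' @export
read_sessions <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}
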
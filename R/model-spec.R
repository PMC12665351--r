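#' Describe an animal model for one trait
#'
#' A model specification names the response, the categorical systematic
#' effects, the continuous covariates and the random terms of a linear animal
#' model. The additive genetic term is always present; a permanent
#' environmental term is added for traits with repeated records.
#'
#' @param response Name of the trait column.
#' @param fixed Character vector of categorical factor columns (may be empty;
#'   an intercept is always fitted).
#' @param covariates Character vector of continuous covariate columns.
#' @param id Name of the individual-id column linking records to the GRM
#'   (default `"sow_id"`).
#' @param permanent_environment Logical; include a per-individual permanent
#'   environmental effect (repeated-record traits).
#' @return Object of class `"model_spec"`.
#' @export
model_spec <- function(response, fixed = character(0),
                       covariates = character(0), id = "sow_id",
                       permanent_environment = FALSE) {
  structure(list(response = response, fixed = fixed, covariates = covariates,
                 id = id, permanent_environment = permanent_environment),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("<model_spec> ", x$response, " ~ ",
      paste(c("1", x$fixed, x$covariates), collapse = " + "),
      " + animal", if (x$permanent_environment) " + pe", "\n", sep = "")
  invisible(x)
}

#' Build design matrices for an animal model
#'
#' Expands the systematic effects into a full-column-rank fixed-effect matrix
#' `X` (treatment contrasts, reference level dropped), and maps records to
#' individuals of the relationship matrix. Factors with a single observed
#' level are dropped with a warning; a rank-deficient `X` is an error naming
#' the aliased columns, and records whose id is absent from the GRM are an
#' error listing those ids.
#'
#' @param records Data frame of phenotypic records (one row per record).
#' @param spec A [model_spec()].
#' @param grm_ids Character vector of individual ids in GRM order.
#' @return List with `y` (response vector), `X`, `id_index` (record ->
#'   GRM-row index; this is the incidence mapping for both the additive and,
#'   when present, the permanent environmental term), `spec`, and `xlev`
#'   (factor levels used).
#' @export
build_design <- function(records, spec, grm_ids) {
  records <- as.data.frame(records)
  vars <- c(spec$response, spec$fixed, spec$covariates, spec$id)
  miss_cols <- setdiff(vars, names(records))
  if (length(miss_cols) > 0) {
    stop("records lack column(s): ", paste(miss_cols, collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(records[vars])) {
    stop("missing values in response, effects or ids are not allowed",
         call. = FALSE)
  }
  fixed <- spec$fixed
  for (f in fixed) records[[f]] <- factor(records[[f]])
  single <- fixed[vapply(fixed, function(f) nlevels(records[[f]]) < 2,
                         logical(1))]
  if (length(single) > 0) {
    warning("factor(s) with a single level dropped from X: ",
            paste(single, collapse = ", "), call. = FALSE)
    fixed <- setdiff(fixed, single)
  }
  terms <- c(fixed, spec$covariates)
  form <- if (length(terms) == 0) ~1 else
    stats::reformulate(terms)
  X <- stats::model.matrix(form, data = records)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; aliased column(s): ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  ids <- as.character(records[[spec$id]])
  id_index <- match(ids, as.character(grm_ids))
  if (anyNA(id_index)) {
    stop("record id(s) absent from the GRM: ",
         paste(unique(ids[is.na(id_index)]), collapse = ", "), call. = FALSE)
  }
  list(y = as.numeric(records[[spec$response]]), X = X, id_index = id_index,
       spec = spec, xlev = lapply(records[fixed], levels))
}

#' Bidirectional stepwise selection of systematic effects
#'
#' Selects the systematic effects for a trait by ordinary least squares:
#' a full model over the candidate effects is refined by bidirectional
#' AIC-based stepwise search (via [MASS::stepAIC()]), after which terms whose
#' partial F-test p-value is at or above `alpha` are removed one at a time
#' (worst first). Deterministic given the input order of candidates.
#'
#' @param records Data frame of records.
#' @param response Response column name.
#' @param candidates Character vector of candidate effect columns (factors or
#'   covariates).
#' @param alpha Retention threshold for the partial F-test (default 0.05).
#' @return Character vector of selected effect names (possibly empty =
#'   intercept-only, with a warning when no candidates were supplied).
#' @export
stepwise_select <- function(records, response, candidates, alpha = 0.05) {
  if (length(candidates) == 0) {
    warning("no candidate effects; returning intercept-only model",
            call. = FALSE)
    return(character(0))
  }
  records <- as.data.frame(records)[c(response, candidates)]
  full <- stats::lm(stats::reformulate(candidates, response), data = records)
  sel <- MASS::stepAIC(
    full, direction = "both", trace = 0,
    scope = list(lower = stats::reformulate("1", response),
                 upper = stats::formula(full)))
  repeat {
    terms_now <- attr(stats::terms(sel), "term.labels")
    if (length(terms_now) == 0) break
    d1 <- stats::drop1(sel, test = "F")
    pvals <- d1[["Pr(>F)"]][-1]
    if (all(pvals < alpha)) break
    worst <- terms_now[which.max(pvals)]
    sel <- stats::update(sel, stats::as.formula(paste(". ~ . -", worst)))
  }
  attr(stats::terms(sel), "term.labels")
}
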
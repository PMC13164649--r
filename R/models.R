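#' Model families of the ensemble
#'
#' The ensemble combines four binary-suitability classifiers that differ in
#' flexibility and bias-variance behaviour:
#'
#' * `linear_logistic` (GLM): unpenalized maximum-likelihood logistic
#'   regression with linear terms. If the fit is perfectly separable, a
#'   weakly ridge-penalized fit is substituted with a warning.
#' * `smooth_additive_logistic` (GAM): penalized cubic regression splines,
#'   about 10 basis functions per predictor, smoothness chosen by
#'   generalized cross-validation (via mgcv).
#' * `elastic_net_logistic` (GLMnet): elastic-net logistic regression,
#'   mixing parameter 0.5, penalty chosen by internal 5-fold
#'   cross-validation (via glmnet).
#' * `randomized_tree_ensemble` (RF): random forest with 500 trees,
#'   `floor(sqrt(p))` candidate predictors per split, unlimited depth
#'   (via randomForest).
#'
#' These defaults are fixed by this package so results are reproducible;
#' no per-species tuning is performed, matching the standard protocol for
#' rare, data-limited species. No class weighting is applied: the
#' presence:background imbalance (typically 1:10) is part of the design.
#'
#' @name model_families
NULL

MODEL_FAMILIES <- c("linear_logistic", "smooth_additive_logistic",
                    "elastic_net_logistic", "randomized_tree_ensemble")

FAMILY_ALIASES <- c(glm = "linear_logistic", gam = "smooth_additive_logistic",
                    glmnet = "elastic_net_logistic",
                    rf = "randomized_tree_ensemble")

#' @rdname model_families
#' @param family Family name or alias (`glm`, `gam`, `glmnet`, `rf`).
#' @return `canonical_family()` returns the canonical family name.
#' @export
canonical_family <- function(family) {
  stopifnot(is.character(family), length(family) == 1L)
  if (family %in% MODEL_FAMILIES) return(family)
  if (family %in% names(FAMILY_ALIASES)) return(unname(FAMILY_ALIASES[family]))
  stop(sprintf("unknown model family '%s' (choose from: %s)", family,
               paste(c(MODEL_FAMILIES, names(FAMILY_ALIASES)), collapse = ", ")))
}

check_fit_table <- function(table) {
  preds <- pb_predictors(table)
  if (length(unique(table$label)) < 2L)
    stop("both classes (presence and background) must be present to fit")
  miss <- which(!stats::complete.cases(table[, preds, drop = FALSE]))
  if (length(miss))
    stop(sprintf("missing feature values in row(s): %s",
                 paste(utils::head(miss, 10), collapse = ", ")))
  preds
}

gam_formula <- function(table, preds) {
  terms <- vapply(preds, function(p) {
    k <- min(10L, length(unique(table[[p]])) - 1L)
    if (k >= 4L) sprintf("s(%s, k = %d, bs = \"cr\")", p, k) else p
  }, "")
  stats::as.formula(paste("label ~", paste(terms, collapse = " + ")))
}

#' Fit one model family on a presence-background table
#'
#' @param family One of the four family names (see [model_families]) or an
#'   alias.
#' @param table A [pb_table()] with both classes and no missing features.
#' @param seed Integer seed controlling all internal randomness (tree
#'   bootstraps, cross-validation folds); identical seed and table give
#'   identical fits.
#' @return An object of class `fitted_sdm`: the fitted object plus training
#'   metadata (family, predictor names, class counts, seed).
#' @export
sdm_fit <- function(family, table, seed = 1L) {
  family <- canonical_family(family)
  preds <- check_fit_table(table)
  x <- as.matrix(table[, preds, drop = FALSE])
  y <- table$label
  fallback <- FALSE
  fit <- with_seed(seed, switch(
    family,
    linear_logistic = {
      sep <- FALSE
      g <- withCallingHandlers(
        stats::glm(stats::reformulate(preds, "label"),
                   data = table, family = stats::binomial()),
        warning = function(w) {
          if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
            sep <<- TRUE
          invokeRestart("muffleWarning")
        })
      if (sep) {
        # perfect separation: weakly ridge-penalized maximum likelihood
        fallback <- TRUE
        warning("perfect separation in linear_logistic; using a weakly penalized fit")
        glmnet::glmnet(x, y, family = "binomial", alpha = 0, lambda = 1e-3)
      } else g
    },
    smooth_additive_logistic =
      mgcv::gam(gam_formula(table, preds), data = table,
                family = stats::binomial(), method = "GCV.Cp"),
    elastic_net_logistic = {
      foldid <- sample(rep_len(1:5, nrow(x)))
      glmnet::cv.glmnet(x, y, family = "binomial", alpha = 0.5,
                        foldid = foldid)
    },
    randomized_tree_ensemble =
      randomForest::randomForest(
        x = x, y = factor(y, levels = c(0, 1)),
        ntree = 500, mtry = max(1L, floor(sqrt(length(preds)))))
  ))
  structure(list(family = family, fit = fit, predictors = preds,
                 n_presence = sum(y == 1L), n_background = sum(y == 0L),
                 seed = seed, penalized_fallback = fallback),
            class = "fitted_sdm")
}

#' @export
print.fitted_sdm <- function(x, ...) {
  cat(sprintf("<fitted_sdm> %s on %d presence / %d background rows (%d predictors)\n",
              x$family, x$n_presence, x$n_background, length(x$predictors)))
  invisible(x)
}

predict_rows <- function(model, newdata) {
  preds <- model$predictors
  missing <- setdiff(preds, names(newdata))
  if (length(missing))
    stop(sprintf("predictor(s) missing from new data: %s",
                 paste(missing, collapse = ", ")))
  x <- as.matrix(newdata[, preds, drop = FALSE])
  p <- switch(
    model$family,
    linear_logistic =
      if (model$penalized_fallback)
        as.numeric(stats::predict(model$fit, newx = x, type = "response"))
      else
        as.numeric(stats::predict(model$fit,
                                  newdata = as.data.frame(newdata),
                                  type = "response")),
    smooth_additive_logistic =
      as.numeric(stats::predict(model$fit,
                                newdata = as.data.frame(newdata),
                                type = "response")),
    elastic_net_logistic =
      as.numeric(stats::predict(model$fit, newx = x, s = "lambda.min",
                                type = "response")),
    randomized_tree_ensemble =
      as.numeric(stats::predict(model$fit, newdata = x, type = "prob")[, "1"])
  )
  pmin(pmax(p, 0), 1)
}

#' Predict presence probability
#'
#' Predicts per-row probabilities on a feature table, or a per-cell
#' probability surface on an environmental stack (nodata cells propagate).
#' Both code paths use the same underlying predictor, so a stack prediction
#' equals the point prediction at every cell center.
#'
#' @param model A `fitted_sdm`.
#' @param newdata A data.frame with the training predictor columns, or an
#'   [env_stack()].
#' @return Numeric vector of probabilities in 0..1, or a
#'   [suitability_map()] when `newdata` is a stack.
#' @export
predict_prob <- function(model, newdata) {
  stopifnot(inherits(model, "fitted_sdm"))
  if (inherits(newdata, "env_stack")) {
    missing <- setdiff(model$predictors, names(newdata$layers))
    if (length(missing))
      stop(sprintf("predictor(s) missing from stack: %s",
                   paste(missing, collapse = ", ")))
    spec <- newdata$spec
    mask <- land_mask(newdata)
    idx <- which(as.vector(t(mask)))               # row-major cell ids
    df <- data.frame(row.names = seq_along(idx))
    for (nm in model$predictors)
      df[[nm]] <- as.vector(t(newdata$layers[[nm]]))[idx]
    p <- predict_rows(model, df)
    vals <- rep(NA_real_, spec$n_rows * spec$n_cols)
    vals[idx] <- p
    suitability_map(spec, matrix(vals, spec$n_rows, spec$n_cols, byrow = TRUE))
  } else {
    predict_rows(model, newdata)
  }
}
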
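#' TSS-derived ensemble weights
#'
#' Converts replicated evaluation records into per-family ensemble weights:
#' each family's weight is its mean test TSS across replicates (and
#' background sets), floored at zero, normalized to sum to one. Families
#' with no skill (mean TSS <= 0) therefore drop out of the consensus; if no
#' family has positive skill the ensemble is undefined and an error is
#' raised.
#'
#' @param records data.frame of evaluation records with columns `family`
#'   and `tss` (as produced by [replicate_evaluate()], possibly row-bound
#'   across background sets).
#' @return Named numeric vector of class `ensemble_weights` summing to 1,
#'   with attribute `mean_tss` (the per-family means it was derived from).
#' @examples
#' rec <- data.frame(family = c("rf", "gam", "glm", "glmnet"),
#'                   tss = c(0.75, 0.62, 0.49, 0.48))
#' tss_weights(rec)   # 0.3205 0.2650 0.2094 0.2051
#' @export
tss_weights <- function(records) {
  stopifnot(is.data.frame(records), all(c("family", "tss") %in% names(records)),
            nrow(records) >= 1L)
  mean_tss <- tapply(records$tss, records$family, mean)
  w <- pmax(as.numeric(mean_tss), 0)
  names(w) <- names(mean_tss)
  if (sum(w) <= 0) stop("no family has positive mean TSS; ensemble undefined")
  w <- w / sum(w)
  structure(w, mean_tss = as.numeric(mean_tss), class = "ensemble_weights")
}

#' @export
print.ensemble_weights <- function(x, ...) {
  cat("<ensemble_weights>\n")
  print(round(unclass(x), 4))
  invisible(x)
}

#' Weighted ensemble prediction surface
#'
#' Per-cell weighted mean of the member family suitability maps: a convex
#' combination, so the ensemble lies between the per-cell minimum and
#' maximum of its members. Nodata in any member propagates to the output.
#'
#' @param maps Named list of [suitability_map()]s, names matching the
#'   weight names.
#' @param weights An [tss_weights()] result (or named non-negative vector
#'   summing to 1).
#' @return A `suitability_map`.
#' @export
ensemble_predict <- function(maps, weights) {
  stopifnot(is.list(maps), length(maps) >= 1L, !is.null(names(maps)))
  fams <- names(weights)
  if (!setequal(fams, names(maps)))
    stop("map names and weight names do not match")
  if (abs(sum(weights) - 1) > 1e-9 || any(weights < 0))
    stop("weights must be non-negative and sum to 1")
  spec <- maps[[1L]]$spec
  for (m in maps) {
    stopifnot(inherits(m, "suitability_map"))
    stop_if_not_conformal(spec, m$spec, "suitability maps")
  }
  acc <- matrix(0, spec$n_rows, spec$n_cols)
  for (f in fams) acc <- acc + unclass(weights)[[f]] * maps[[f]]$values
  suitability_map(spec, acc)
}

#' Cell-wise mean composite of species maps
#'
#' Per-cell arithmetic mean across species-level ensemble maps, summarizing
#' genus-level habitat concentration (e.g. for identifying multi-species
#' conservation hotspots).
#'
#' @param maps List of conformal [suitability_map()]s.
#' @return A `suitability_map`.
#' @export
composite_mean <- function(maps) {
  stopifnot(is.list(maps), length(maps) >= 1L)
  spec <- maps[[1L]]$spec
  acc <- matrix(0, spec$n_rows, spec$n_cols)
  for (m in maps) {
    stopifnot(inherits(m, "suitability_map"))
    stop_if_not_conformal(spec, m$spec, "suitability maps")
    acc <- acc + m$values
  }
  suitability_map(spec, acc / length(maps))
}

#' Permutation variable importance
#'
#' Importance of each predictor as the mean decrease in discrimination
#' (AUC) when that predictor's column is randomly permuted: the metric on
#' the intact table minus the mean metric over `n_perm` within-column
#' permutations. Computed per family and aggregated across families by the
#' ensemble weights. Raw aggregated values are retained; a floored-at-zero
#' copy is provided for reporting, since small negative values arise from
#' Monte-Carlo noise on irrelevant predictors.
#'
#' @param models Named list of `fitted_sdm` objects (names = families).
#' @param weights [tss_weights()] over the same families.
#' @param table A [pb_table()] to evaluate on.
#' @param n_perm Permutations per predictor (default 10).
#' @param seed Integer seed.
#' @return List of class `importance_table`: `per_model` (data.frame
#'   family/variable/importance) and `aggregated` (data.frame
#'   variable/importance_raw/importance, sorted descending).
#' @export
permutation_importance <- function(models, weights, table, n_perm = 10L,
                                   seed = 1L) {
  stopifnot(is.list(models), length(models) >= 1L, !is.null(names(models)),
            n_perm >= 1L)
  if (!setequal(names(models), names(weights)))
    stop("model names and weight names do not match")
  vars <- pb_predictors(table)
  labels <- table$label
  per_model <- list()
  for (f in names(models)) {
    base <- auc(predict_prob(models[[f]], table), labels)
    for (v in vars) {
      drops <- numeric(n_perm)
      for (p in seq_len(n_perm)) {
        perm <- with_seed(derive_seed(seed, "perm", f, v, p),
                          sample(nrow(table)))
        tp <- table
        tp[[v]] <- table[[v]][perm]
        drops[p] <- base - auc(predict_prob(models[[f]], tp), labels)
      }
      per_model[[length(per_model) + 1L]] <-
        data.frame(family = f, variable = v, importance = mean(drops))
    }
  }
  per_model <- do.call(rbind, per_model)
  agg <- vapply(vars, function(v) {
    sum(vapply(names(models), function(f)
      unclass(weights)[[f]] *
        per_model$importance[per_model$family == f & per_model$variable == v],
      0))
  }, 0)
  aggregated <- data.frame(variable = vars, importance_raw = unname(agg),
                           importance = pmax(unname(agg), 0))
  aggregated <- aggregated[order(-aggregated$importance_raw), ]
  rownames(aggregated) <- NULL
  structure(list(per_model = per_model, aggregated = aggregated),
            class = "importance_table")
}

#' @export
print.importance_table <- function(x, ...) {
  cat("<importance_table> aggregated ranking:\n")
  print(x$aggregated, row.names = FALSE)
  invisible(x)
}

#' Percentile-based suitability classes
#'
#' Bins a suitability map into `n_bins` classes of (near-)equal cell count
#' using empirical percentile edges (for six bins: 16.7/33.3/50/66.7/83.3%),
#' the binning used for high-contrast composite suitability displays.
#'
#' @param map A [suitability_map()] with at least `n_bins` distinct values.
#' @param n_bins Number of classes (default 6).
#' @return Integer matrix of class codes 1..`n_bins` (`NA` = nodata), with
#'   attribute `breaks`.
#' @export
percentile_bins <- function(map, n_bins = 6L) {
  stopifnot(inherits(map, "suitability_map"), n_bins >= 2L)
  v <- map$values[!is.na(map$values)]
  if (length(unique(v)) < n_bins)
    stop(sprintf("need at least %d distinct values to form %d percentile bins",
                 n_bins, n_bins))
  br <- stats::quantile(v, probs = seq(0, 1, length.out = n_bins + 1),
                        type = 7, names = FALSE)
  if (anyDuplicated(br))
    stop("degenerate percentile edges (too many tied values)")
  cls <- matrix(.bincode(map$values, br, include.lowest = TRUE),
                map$spec$n_rows, map$spec$n_cols)
  attr(cls, "breaks") <- br
  cls
}
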
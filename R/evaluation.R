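#' Discrimination and calibration metrics
#'
#' Threshold-independent and threshold-dependent skill metrics for
#' presence-background scores. `auc()` is the rank-based (Mann-Whitney)
#' area under the ROC curve with ties counted one half: the probability
#' that a random presence scores above a random background point.
#' `point_biserial_cor()` is the Pearson correlation between scores and the
#' 0/1 labels. `tss()` maximizes sensitivity + specificity - 1 over all
#' observed score thresholds (prediction rule `score >= t`; smallest
#' maximizing threshold on ties). `binomial_deviance()` is the mean scaled
#' binomial deviance `-(2/n) sum(y log p + (1-y) log(1-p))` with
#' probabilities clipped to `[1e-6, 1 - 1e-6]`.
#'
#' @param scores Numeric prediction scores (probabilities for deviance).
#' @param labels Binary labels, 1 = presence, 0 = background; both classes
#'   must be present (except deviance).
#' @return `auc()`: a number in 0..1. `point_biserial_cor()`: in -1..1.
#'   `tss()`: list with `tss` (in -1..1) and `threshold`.
#'   `binomial_deviance()`: a non-negative number.
#' @examples
#' auc(c(0.9, 0.8, 0.4, 0.3), c(1, 0, 1, 0))   # 0.75
#' tss(c(0.9, 0.8, 0.4, 0.3), c(1, 0, 1, 0))$tss  # 0.5
#' @name metrics
NULL

check_two_class <- function(labels) {
  stopifnot(all(labels %in% c(0, 1)))
  if (length(unique(labels)) < 2L)
    stop("both classes must be present")
}

#' @rdname metrics
#' @export
auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), !anyNA(scores))
  check_two_class(labels)
  r <- rank(scores)                      # midranks handle ties as 1/2
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' @rdname metrics
#' @export
point_biserial_cor <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), !anyNA(scores))
  check_two_class(labels)
  if (stats::sd(scores) == 0) stop("scores have zero variance")
  stats::cor(scores, labels)
}

#' @rdname metrics
#' @export
tss <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), !anyNA(scores))
  check_two_class(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  th <- sort(unique(scores))
  best <- -Inf; best_t <- th[1]
  for (t in th) {
    pred <- scores >= t
    sens <- sum(pred & labels == 1) / n1
    spec <- sum(!pred & labels == 0) / n0
    v <- sens + spec - 1
    if (v > best + 1e-12) { best <- v; best_t <- t }
  }
  list(tss = best, threshold = best_t)
}

#' @rdname metrics
#' @export
binomial_deviance <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), !anyNA(scores),
            all(scores >= 0 & scores <= 1), all(labels %in% c(0, 1)))
  p <- pmin(pmax(scores, 1e-6), 1 - 1e-6)
  -2 * mean(labels * log(p) + (1 - labels) * log(1 - p))
}

evaluate_scores <- function(scores, labels) {
  t <- tss(scores, labels)
  data.frame(auc = auc(scores, labels),
             cor = point_biserial_cor(scores, labels),
             tss = t$tss, threshold = t$threshold,
             deviance = binomial_deviance(scores, labels))
}

# stratified train/test split; redraw until both partitions hold both
# classes (max 100 attempts)
split_stratified <- function(labels, test_fraction, max_tries = 100L) {
  for (i in seq_len(max_tries)) {
    test <- integer()
    for (cl in unique(labels)) {
      rows <- which(labels == cl)
      n_test <- round(test_fraction * length(rows))
      test <- c(test, sample(rows, n_test))
    }
    train <- setdiff(seq_along(labels), test)
    if (length(unique(labels[test])) == 2L &&
        length(unique(labels[train])) == 2L)
      return(list(train = train, test = sort(test)))
  }
  stop("could not draw a two-class train/test split in 100 attempts")
}

split_bootstrap <- function(labels, max_tries = 100L) {
  n <- length(labels)
  for (i in seq_len(max_tries)) {
    train <- sample(n, n, replace = TRUE)
    test <- setdiff(seq_len(n), unique(train))
    if (length(test) >= 2L &&
        length(unique(labels[test])) == 2L &&
        length(unique(labels[train])) == 2L)
      return(list(train = train, test = test))
  }
  stop("could not draw a two-class bootstrap split in 100 attempts")
}

#' Replicated hold-out evaluation
#'
#' Repeatedly partitions the modeling table, fits the family on the
#' training partition and scores the held-out partition with all four
#' metrics. `subsample` uses a stratified random split withholding
#' `test_fraction` of each class; `bootstrap` trains on a bootstrap
#' resample and tests on the out-of-bag rows. Replicates with a
#' single-class partition are redrawn (at most 100 attempts each).
#'
#' @param family Model family (see [model_families]).
#' @param table A [pb_table()].
#' @param scheme `"subsample"` or `"bootstrap"`.
#' @param n_reps Number of replicates (default 10; lower values such as 3
#'   are common when runtime matters more than precision).
#' @param test_fraction Held-out fraction for `subsample` (default 0.30).
#' @param seed Integer seed.
#' @return data.frame with one row per replicate: `family`, `scheme`,
#'   `replicate`, `auc`, `cor`, `tss`, `threshold`, `deviance`.
#' @export
replicate_evaluate <- function(family, table, scheme = c("subsample", "bootstrap"),
                               n_reps = 10L, test_fraction = 0.30, seed = 1L) {
  scheme <- match.arg(scheme)
  family <- canonical_family(family)
  stopifnot(n_reps >= 1L, test_fraction > 0, test_fraction < 1)
  out <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    child <- derive_seed(seed, family, scheme, r)
    parts <- with_seed(child,
      if (scheme == "subsample") split_stratified(table$label, test_fraction)
      else split_bootstrap(table$label))
    m <- sdm_fit(family, pb_rows(table, parts$train),
                 seed = derive_seed(child, "fit"))
    sc <- predict_prob(m, pb_rows(table, parts$test))
    rec <- evaluate_scores(sc, table$label[parts$test])
    out[[r]] <- cbind(data.frame(family = family, scheme = scheme,
                                 replicate = r), rec)
  }
  do.call(rbind, out)
}

#' Assign spatially blocked cross-validation folds
#'
#' Lays square blocks of side `block_km` over the points (in a local
#' equirectangular projection about the data centroid, adequate at the
#' 100-500 km block scales used for autocorrelation control) and randomly
#' allocates occupied blocks to `k` folds. All points in one block share a
#' fold, so test folds are geographically separated from their training
#' data. When `labels` are supplied, allocation is redrawn (up to 100
#' times) until every fold holds at least one presence and one background
#' row.
#'
#' @param coords data.frame or matrix with `lon` and `lat` columns
#'   (degrees).
#' @param block_km Block side length in km (default 200).
#' @param k Number of folds (default 5; requires at least `k` occupied
#'   blocks).
#' @param seed Integer seed.
#' @param labels Optional 0/1 labels for fold-validity redraws.
#' @return data.frame of class `fold_assignment` with one row per point:
#'   `row`, `block` (block id) and `fold` (1..k).
#' @export
assign_spatial_blocks <- function(coords, block_km = 200, k = 5L, seed = 1L,
                                  labels = NULL) {
  coords <- as.data.frame(coords)
  stopifnot(all(c("lon", "lat") %in% names(coords)), block_km > 0, k >= 2L)
  lon0 <- mean(coords$lon); lat0 <- mean(coords$lat)
  x <- EARTH_RADIUS_KM * cos(lat0 * pi / 180) * (coords$lon - lon0) * pi / 180
  y <- EARTH_RADIUS_KM * (coords$lat - lat0) * pi / 180
  block <- paste(floor(x / block_km), floor(y / block_km), sep = ":")
  blocks <- unique(block)
  if (length(blocks) < k)
    stop(sprintf("only %d occupied block(s) for k = %d folds", length(blocks), k))
  fold_of <- with_seed(seed, {
    for (try in seq_len(100L)) {
      f <- sample(rep_len(seq_len(k), length(blocks)))
      names(f) <- blocks
      fold <- f[block]
      ok <- if (is.null(labels)) TRUE else
        all(vapply(seq_len(k), function(i)
          length(unique(labels[fold == i])) == 2L, TRUE))
      if (ok) break
    }
    if (!ok) stop("could not allocate blocks so every fold has both classes")
    f
  })
  structure(data.frame(row = seq_len(nrow(coords)), block = block,
                       fold = unname(fold_of[block])),
            class = c("fold_assignment", "data.frame"))
}

#' Spatial block cross-validation
#'
#' For each fold, fits the family on the other folds and computes AUC on
#' the geographically held-out fold. Comparing the mean spatial-CV AUC with
#' random-split AUC quantifies the performance drop attributable to spatial
#' autocorrelation: a model exploiting spatial clustering rather than
#' environment collapses toward 0.5 under blocked evaluation.
#'
#' @param family Model family.
#' @param table A [pb_table()].
#' @param folds A [assign_spatial_blocks()] result for the table's rows.
#' @param seed Integer seed for the per-fold fits.
#' @return List with `per_fold` (data.frame fold/n_test/auc) and `mean_auc`.
#'   Folds whose training or test partition is single-class are skipped
#'   with a warning; fewer than 2 usable folds is an error.
#' @export
spatial_cv <- function(family, table, folds, seed = 1L) {
  family <- canonical_family(family)
  stopifnot(inherits(folds, "fold_assignment"), nrow(folds) == nrow(table))
  ks <- sort(unique(folds$fold))
  rows <- list()
  for (f in ks) {
    test <- which(folds$fold == f); train <- which(folds$fold != f)
    if (length(unique(table$label[test])) < 2L ||
        length(unique(table$label[train])) < 2L) {
      warning(sprintf("fold %d skipped: single-class partition", f))
      next
    }
    m <- sdm_fit(family, pb_rows(table, train), seed = derive_seed(seed, "cv", f))
    sc <- predict_prob(m, pb_rows(table, test))
    rows[[length(rows) + 1L]] <-
      data.frame(fold = f, n_test = length(test),
                 auc = auc(sc, table$label[test]))
  }
  if (length(rows) < 2L) stop("fewer than 2 usable folds")
  per_fold <- do.call(rbind, rows)
  list(per_fold = per_fold, mean_auc = mean(per_fold$auc))
}

#' Null-model significance test
#'
#' Tests whether observed model skill exceeds what randomly placed
#' occurrences achieve. The full fit-and-evaluate pipeline (supplied as a
#' closure) is repeated on `n_presences` locations drawn uniformly at
#' random from the terrestrial cells of the extent; the observed AUC is
#' significant when it exceeds the stated empirical percentile (default
#' 95th) of the null AUC distribution. Failed null replicates are redrawn,
#' up to `2 * n_null` total attempts.
#'
#' @param observed_auc AUC of the model fitted on the real presences.
#' @param spec The [grid_spec()] of the extent.
#' @param mask Logical matrix; TRUE marks cells presences may fall in.
#' @param n_presences Number of random presences per null replicate.
#' @param fit_fun Closure `function(coords, seed)` receiving a data.frame
#'   of lon/lat presence locations and returning a test AUC; it should
#'   reproduce the real pipeline (background sampling, fitting,
#'   evaluation).
#' @param n_null Number of null replicates (default 99; at least 19).
#' @param level Percentile defining the critical value (default 0.95).
#' @param seed Integer seed.
#' @return List of class `null_distribution`: `null_auc`, `observed`,
#'   `critical` (the `level` percentile of the null values), `significant`
#'   (`observed > critical`), `level`.
#' @export
null_model_test <- function(observed_auc, spec, mask, n_presences, fit_fun,
                            n_null = 99L, level = 0.95, seed = 1L) {
  stopifnot(inherits(spec, "grid_spec"), n_null >= 19L,
            level > 0, level < 1, n_presences >= 1)
  check_layer_dim(spec, mask, "mask")
  centers <- cell_centers(spec)
  land <- which(as.vector(t(mask)))
  if (length(land) < n_presences)
    stop("fewer eligible cells than presences to randomize")
  nulls <- numeric(0)
  attempts <- 0L
  while (length(nulls) < n_null && attempts < 2L * n_null) {
    attempts <- attempts + 1L
    child <- derive_seed(seed, "null", attempts)
    picked <- with_seed(child, sample(land, n_presences))
    coords <- data.frame(lon = centers$lon[picked], lat = centers$lat[picked])
    v <- tryCatch(fit_fun(coords, child), error = function(e) NA_real_)
    if (!is.na(v)) nulls <- c(nulls, v)
  }
  if (length(nulls) < n_null)
    stop(sprintf("only %d of %d null replicates succeeded", length(nulls), n_null))
  critical <- unname(stats::quantile(nulls, level, type = 7))
  structure(list(null_auc = nulls, observed = observed_auc,
                 critical = critical, significant = observed_auc > critical,
                 level = level),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf(
    "<null_distribution> observed AUC %.3f vs %d%% null critical %.3f: %s\n",
    x$observed, round(100 * x$level), x$critical,
    if (x$significant) "significant" else "not significant"))
  invisible(x)
}
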
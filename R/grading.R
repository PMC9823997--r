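#' EU egg weight-grade table
#'
#' The European egg size standard: grade 1 "XL" above 73 g, grade 2 "L" above
#' 63 up to 73 g, grade 3 "M" above 53 up to 63 g, grade 4 "S" up to 53 g.
#' Each band is the half-open interval `(lower_g, upper_g]`; 53 g exactly is
#' graded S so that the bands partition the positive axis (the printed
#' standard leaves 53 g unassigned between "<53" and ">53").
#'
#' @return A data frame with columns `grade`, `lower_g`, `upper_g`, `label`.
#' @export
eu_grade_table <- function() {
  data.frame(
    grade = 1:4,
    lower_g = c(73, 63, 53, 0),
    upper_g = c(Inf, 73, 63, 53),
    label = c("XL", "L", "M", "S"),
    stringsAsFactors = FALSE
  )
}

#' Validate that a grade table partitions the positive weights
#'
#' Checks that the bands `(lower_g, upper_g]` are non-overlapping and cover
#' `(0, Inf)` with no gap.
#'
#' @param table A grade table as returned by [eu_grade_table()].
#' @return `TRUE` invisibly; errors otherwise.
#' @export
validate_grade_table <- function(table) {
  stopifnot(all(c("grade", "lower_g", "upper_g", "label") %in% names(table)))
  tab <- table[order(table$lower_g), ]
  if (any(tab$upper_g <= tab$lower_g)) stop("empty band in grade table")
  if (tab$lower_g[1] != 0) stop("grade table does not reach down to 0 g")
  if (!is.infinite(tab$upper_g[nrow(tab)]))
    stop("grade table does not extend to +Inf")
  if (nrow(tab) > 1 &&
      any(tab$lower_g[-1] != tab$upper_g[-nrow(tab)]))
    stop("grade bands overlap or leave a gap")
  invisible(TRUE)
}

#' Assign weight grades
#'
#' Maps weights in grams to their grade band `(lower_g, upper_g]`.
#'
#' @param weight_g Numeric vector of positive weights in grams.
#' @param table Grade table, default [eu_grade_table()].
#' @return Data frame with columns `weight_g`, `grade`, `label`.
#' @export
#' @examples
#' assign_grade(c(45, 58, 68, 75))
assign_grade <- function(weight_g, table = eu_grade_table()) {
  if (any(!is.finite(weight_g) | weight_g <= 0))
    stop("weights must be positive and finite")
  validate_grade_table(table)
  tab <- table[order(table$lower_g), ]
  # weight w belongs to the band with the largest lower_g strictly below w
  idx <- findInterval(weight_g, tab$lower_g, left.open = TRUE)
  data.frame(weight_g = weight_g,
             grade = tab$grade[idx],
             label = tab$label[idx],
             stringsAsFactors = FALSE)
}

#' Fit the area-to-weight calibration
#'
#' Ordinary least-squares regression of true weight on geometric features
#' (by default the dirt-corrected projected area). The data are split at
#' random into a training portion of size `round(train_fraction * n)` and a
#' held-out test portion; coefficients come from the training portion and
#' R-squared is reported on both.
#'
#' @param features Data frame (or matrix) of numeric features, one row per
#'   egg. Column names become the model's feature names.
#' @param weights_g True weights in grams, one per row of `features`.
#' @param train_fraction Fraction of rows used for training, in (0, 1).
#'   Default 0.67.
#' @param seed Integer seed for the random split.
#' @param feature_names Optional subset of feature columns to use.
#' @return An object of class `calibration_model` with elements
#'   `feature_names`, `coefficients` (named, per feature), `intercept`,
#'   `train_fraction`, `seed`, `train_idx` and `fit_diagnostics`
#'   (`r2_train`, `r2_test`, `n_train`, `n_test`).
#' @export
fit_calibration <- function(features, weights_g, train_fraction = 0.67,
                            seed = 1L, feature_names = NULL) {
  features <- as.data.frame(features)
  if (!is.null(feature_names)) {
    missing <- setdiff(feature_names, names(features))
    if (length(missing))
      stop("missing feature(s): ", paste(missing, collapse = ", "))
    features <- features[feature_names]
  }
  n <- nrow(features)
  if (n < 3) stop("need at least 3 samples to calibrate")
  if (length(weights_g) != n)
    stop("`weights_g` must have one entry per feature row")
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("`train_fraction` must be strictly inside (0, 1)")
  n_train <- as.integer(round(train_fraction * n))
  n_train <- max(2L, min(n - 1L, n_train))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  train_idx <- sort(sample.int(n, n_train))
  x_train <- as.matrix(features[train_idx, , drop = FALSE])
  qrx <- qr(cbind(1, x_train))
  if (qrx$rank < ncol(x_train) + 1) {
    stop("rank-deficient design; collinear feature(s) among: ",
         paste(names(features), collapse = ", "))
  }
  fit <- stats::lm.fit(cbind(`(Intercept)` = 1, x_train), weights_g[train_idx])
  coefs <- fit$coefficients
  model <- structure(list(
    feature_names = names(features),
    coefficients = coefs[-1],
    intercept = unname(coefs[1]),
    train_fraction = train_fraction,
    seed = as.integer(seed),
    train_idx = train_idx
  ), class = "calibration_model")
  pred <- predict_weight(model, features)
  r2 <- function(idx) {
    a <- weights_g[idx]; p <- pred[idx]
    1 - sum((a - p)^2) / sum((a - mean(a))^2)
  }
  model$fit_diagnostics <- list(
    r2_train = r2(train_idx),
    r2_test = r2(setdiff(seq_len(n), train_idx)),
    n_train = n_train,
    n_test = n - n_train
  )
  model
}

#' @export
print.calibration_model <- function(x, ...) {
  cat("<calibration_model>\n  weight_g =", format(x$intercept, digits = 6))
  for (nm in x$feature_names)
    cat(sprintf(" + %s * %s", format(x$coefficients[[nm]], digits = 6), nm))
  cat("\n")
  d <- x$fit_diagnostics
  if (!is.null(d))
    cat(sprintf("  R2 train %.4f (n=%d), R2 test %.4f (n=%d)\n",
                d$r2_train, d$n_train, d$r2_test, d$n_test))
  invisible(x)
}

#' Predict egg weight from geometric features
#'
#' Affine prediction from a fitted [fit_calibration()] model, clipped below
#' at zero (a silhouette cannot weigh a negative amount).
#'
#' @param model A `calibration_model`.
#' @param features Data frame containing (at least) the model's features.
#' @return Numeric vector of predicted weights in grams.
#' @export
predict_weight <- function(model, features) {
  features <- as.data.frame(features)
  missing <- setdiff(model$feature_names, names(features))
  if (length(missing))
    stop("missing feature(s): ", paste(missing, collapse = ", "))
  x <- as.matrix(features[model$feature_names])
  pmax(0, drop(x %*% model$coefficients) + model$intercept)
}

#' Evaluate weight predictions against true weights
#'
#' Computes the coefficient of determination (R-squared, computed as
#' \eqn{1 - SS_{res}/SS_{tot}} of actual vs predicted), the mean absolute
#' percentage error, and per-grade summaries: classification accuracy
#' (grade from predicted weight vs grade from actual weight), mean and
#' standard deviation of the absolute percentage error, and measurement
#' accuracy (100 minus the mean absolute percentage error).
#'
#' @param predicted_g,actual_g Numeric vectors of equal length (>= 2).
#' @param table Grade table, default [eu_grade_table()].
#' @return A list with `r2`, `mape_pct`, `overall_class_accuracy_pct`,
#'   `r2_defined`, and a data frame `per_grade`.
#' @export
evaluate_grading <- function(predicted_g, actual_g, table = eu_grade_table()) {
  n <- length(actual_g)
  if (length(predicted_g) != n || n < 2)
    stop("`predicted_g` and `actual_g` must have equal length >= 2")
  ss_tot <- sum((actual_g - mean(actual_g))^2)
  r2_defined <- ss_tot > 0
  r2 <- if (r2_defined) 1 - sum((actual_g - predicted_g)^2) / ss_tot else NA_real_
  pct_err <- 100 * abs(predicted_g - actual_g) / actual_g
  g_true <- assign_grade(actual_g, table)
  g_pred <- assign_grade(pmax(predicted_g, .Machine$double.eps), table)
  per <- lapply(split(seq_len(n), g_true$grade), function(idx) {
    data.frame(
      grade = g_true$grade[idx[1]],
      label = g_true$label[idx[1]],
      n = length(idx),
      class_accuracy_pct = 100 * mean(g_pred$grade[idx] == g_true$grade[idx]),
      mean_abs_pct_err = mean(pct_err[idx]),
      sd_pct_err = stats::sd(pct_err[idx]),
      measurement_accuracy_pct = 100 - mean(pct_err[idx]),
      stringsAsFactors = FALSE
    )
  })
  per <- do.call(rbind, per)
  per <- per[order(per$grade), ]
  rownames(per) <- NULL
  list(
    r2 = r2,
    r2_defined = r2_defined,
    mape_pct = mean(pct_err),
    overall_class_accuracy_pct = 100 * mean(g_pred$grade == g_true$grade),
    per_grade = per
  )
}

#' Write / read a calibration model as JSON
#'
#' @param model A `calibration_model`.
#' @param path File path for the JSON model.
#' @return `read_calibration()` returns the `calibration_model`;
#'   `write_calibration()` returns `path` invisibly.
#' @export
write_calibration <- function(model, path) {
  obj <- list(
    feature_names = model$feature_names,
    coefficients = as.list(model$coefficients),
    intercept = model$intercept,
    train_fraction = model$train_fraction,
    seed = model$seed,
    diagnostics = model$fit_diagnostics
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(
    feature_names = obj$feature_names,
    coefficients = unlist(obj$coefficients),
    intercept = obj$intercept,
    train_fraction = obj$train_fraction,
    seed = obj$seed,
    fit_diagnostics = obj$diagnostics
  ), class = "calibration_model")
}

# save/restore the global RNG state so seeded helpers do not disturb callers
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
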
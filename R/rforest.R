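#' Random-forest regression with permutation importance
#'
#' Bagged CART-style regression trees: each tree is grown on a bootstrap
#' sample and considers a random subset of `mtry` predictors (default a
#' third of the available variables) at every split. Variable importance is
#' the mean increase in out-of-bag MSE when a predictor is permuted among
#' each tree's out-of-bag rows; model quality is reported as out-of-bag
#' r-squared. The forest is insensitive to predictor collinearity in the
#' way coefficient-based models are not, which is why it backs up the OLS
#' comparisons.
#'
#' @param table data.frame with no missing values in the used columns.
#' @param response response column name.
#' @param predictors numeric predictor column names (at least one).
#' @param n_trees number of trees, default 500.
#' @param mtry predictors tried per split; default `max(1, floor(p / 3))`.
#' @param min_node minimal node size eligible for splitting, default 5.
#' @param seed RNG seed for bagging/splits/permutations.
#' @param importance compute permutation importance (default `TRUE`).
#' @return An `rf_fit`: `importance` (named), `oob_r2`, `oob_pred`,
#'   `n_trees`, `mtry`, `seed`, and the tree ensemble for [predict()].
#' @export
rf_regression <- function(table, response, predictors, n_trees = 500L,
                          mtry = NULL, min_node = 5L, seed = NULL,
                          importance = TRUE) {
  if (length(predictors) == 0L) stop("at least one predictor is required")
  missing_cols <- setdiff(c(response, predictors), names(table))
  if (length(missing_cols)) {
    stop("column(s) absent from the table: ",
         paste(missing_cols, collapse = ", "))
  }
  X <- as.matrix(table[, predictors, drop = FALSE])
  storage.mode(X) <- "double"
  y <- as.numeric(table[[response]])
  if (anyNA(X) || anyNA(y)) stop("missing values in model columns")
  if (is.null(mtry)) mtry <- max(1L, floor(length(predictors) / 3))
  fit <- with_seed(seed, rf_fit_cpp(X, y, as.integer(n_trees),
                                    as.integer(mtry), as.integer(min_node),
                                    isTRUE(importance)))
  oob <- fit$oob_pred
  ok <- !is.na(oob)
  oob_r2 <- 1 - mean((y[ok] - oob[ok])^2) / mean((y[ok] - mean(y[ok]))^2)
  imp <- if (isTRUE(importance)) {
    stats::setNames(fit$importance, predictors)
  } else NULL
  structure(list(n_trees = as.integer(n_trees), mtry = as.integer(mtry),
                 min_node = as.integer(min_node), seed = seed,
                 predictors = predictors, response = response,
                 importance = imp, oob_r2 = oob_r2, oob_pred = oob,
                 trees = fit$trees),
            class = "rf_fit")
}

#' @export
print.rf_fit <- function(x, ...) {
  cat(sprintf("<rf_fit> %d trees, mtry = %d, OOB r2 = %.4f\n",
              x$n_trees, x$mtry, x$oob_r2))
  if (!is.null(x$importance)) {
    imp <- sort(x$importance, decreasing = TRUE)
    cat("  importance:", paste(names(imp), round(imp, 4), sep = "=",
                               collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
predict.rf_fit <- function(object, newdata, ...) {
  X <- as.matrix(newdata[, object$predictors, drop = FALSE])
  storage.mode(X) <- "double"
  rf_predict_cpp(object$trees, X)
}
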
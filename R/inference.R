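#' Box-Cox transform and z-standardise columns
#'
#' For each named variable the column is shifted by `max(0, 1e-6 - min(x))`
#' to enforce positivity (FSC cosines can be negative), the Box-Cox power
#' parameter lambda is chosen by maximising the profile log-likelihood over
#' a grid, the transform `(x^lambda - 1) / lambda` (natural log at
#' `lambda = 0`) is applied, and the result is z-standardised. The returned
#' spec allows exact reapplication to new data via [apply_boxcox_z()].
#'
#' @param table data.frame.
#' @param variables names of numeric columns to transform.
#' @param lambda_grid candidate lambdas; default `seq(-2, 2, by = 0.01)`.
#' @param lambda optional named vector forcing lambda for some variables.
#' @return list with `table` (transformed copy) and `spec` (data.frame with
#'   `variable`, `lambda`, `shift`, `mean`, `sd`).
#' @export
boxcox_z <- function(table, variables, lambda_grid = seq(-2, 2, by = 0.01),
                     lambda = NULL) {
  spec <- data.frame(variable = variables, lambda = NA_real_,
                     shift = NA_real_, mean = NA_real_, sd = NA_real_,
                     stringsAsFactors = FALSE)
  for (j in seq_along(variables)) {
    v <- variables[j]
    x <- table[[v]]
    if (is.null(x)) stop("no column named '", v, "'")
    if (anyNA(x)) stop("missing values in '", v, "'")
    if (stats::sd(x) == 0) stop("constant column '", v, "' cannot be transformed")
    shift <- max(0, 1e-6 - min(x))
    y <- x + shift
    lam <- if (!is.null(lambda) && v %in% names(lambda)) {
      lambda[[v]]
    } else {
      ll <- vapply(lambda_grid, boxcox_loglik, numeric(1), y = y)
      lambda_grid[which.max(ll)]
    }
    yt <- boxcox_apply(y, lam)
    mu <- mean(yt); s <- stats::sd(yt)
    table[[v]] <- (yt - mu) / s
    spec[j, c("lambda", "shift", "mean", "sd")] <- c(lam, shift, mu, s)
  }
  list(table = table, spec = spec)
}

boxcox_apply <- function(y, lambda) {
  if (abs(lambda) < 1e-12) log(y) else (y^lambda - 1) / lambda
}

# Profile log-likelihood of the Gaussian Box-Cox model at a given lambda.
boxcox_loglik <- function(y, lambda) {
  n <- length(y)
  yt <- boxcox_apply(y, lambda)
  s2 <- mean((yt - mean(yt))^2)
  -n / 2 * log(s2) + (lambda - 1) * sum(log(y))
}

#' Re-apply a stored Box-Cox/z spec to new data
#'
#' @param spec the `spec` element returned by [boxcox_z()].
#' @param table data.frame containing the spec's variables.
#' @return Transformed copy of `table`.
#' @export
apply_boxcox_z <- function(spec, table) {
  for (j in seq_len(nrow(spec))) {
    v <- spec$variable[j]
    yt <- boxcox_apply(table[[v]] + spec$shift[j], spec$lambda[j])
    table[[v]] <- (yt - spec$mean[j]) / spec$sd[j]
  }
  table
}

#' Fit an ordinary-least-squares model
#'
#' OLS of `response` on `predictors` plus optional two-way interaction
#' terms (products of the supplied — typically already z-scored — columns;
#' main effects are always included). AIC is computed from the Gaussian
#' log-likelihood; the additive-constant convention is selectable and AIC
#' differences between nested fits are invariant to it.
#'
#' @param table data.frame with no missing values in the used columns.
#' @param response response column name.
#' @param predictors character vector of predictor column names.
#' @param interactions list of 2-element character vectors, each adding the
#'   product term of two predictors.
#' @param aic_convention `"loglik"` (full Gaussian log-likelihood, as
#'   `stats::AIC`) or `"rss"` (`n log(RSS/n) + 2p`, dropping constants).
#' @return A `model_fit` with the coefficient table (`beta`, `se`, `t`,
#'   `p`), `aic`, `n`, `r2` and the underlying `lm` fit.
#' @export
fit_linear <- function(table, response, predictors, interactions = NULL,
                       aic_convention = c("loglik", "rss")) {
  aic_convention <- match.arg(aic_convention)
  terms <- predictors
  if (!is.null(interactions)) {
    terms <- c(terms, vapply(interactions, function(p) {
      stopifnot(length(p) == 2L)
      paste(p, collapse = ":")
    }, character(1)))
  }
  used <- unique(c(response, predictors,
                   if (is.null(interactions)) NULL else unlist(interactions)))
  missing_cols <- setdiff(used, names(table))
  if (length(missing_cols)) {
    stop("column(s) absent from the table: ",
         paste(missing_cols, collapse = ", "))
  }
  if (anyNA(table[, used])) stop("missing values in model columns")
  fml <- stats::as.formula(paste(response, "~", paste(terms, collapse = " + ")))
  fit <- stats::lm(fml, data = table)
  cf <- stats::coef(fit)
  if (anyNA(cf)) {
    stop("rank-deficient design; aliased column(s): ",
         paste(names(cf)[is.na(cf)], collapse = ", "))
  }
  sm <- summary(fit)
  ct <- as.data.frame(sm$coefficients)
  names(ct) <- c("beta", "se", "t", "p")
  n <- length(fit$residuals)
  p <- length(cf)
  aic <- if (aic_convention == "loglik") {
    stats::AIC(fit)
  } else {
    rss <- sum(fit$residuals^2)
    n * log(rss / n) + 2 * p
  }
  structure(list(response = response, predictors = terms,
                 coefficients = ct, aic = aic, n = n,
                 r2 = sm$r.squared, convention = aic_convention,
                 formula = fml, model = fit),
            class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat("<model_fit> ", deparse(x$formula), "\n  n = ", x$n,
      ", r2 = ", round(x$r2, 4), ", AIC = ", round(x$aic, 2), "\n", sep = "")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Compare two nested OLS fits by AIC difference
#'
#' `delta_aic = AIC(base) - AIC(augmented)`: positive values mean the
#' augmented model fits better. The two fits must use the same rows and
#' the same AIC convention, and the base predictors must be a subset of
#' the augmented ones.
#'
#' @param base,augmented `model_fit` objects from [fit_linear()].
#' @return A `model_comparison` with fields `base`, `augmented`,
#'   `delta_aic`.
#' @export
compare_models <- function(base, augmented) {
  stopifnot(inherits(base, "model_fit"), inherits(augmented, "model_fit"))
  if (base$n != augmented$n) {
    stop("models fit to different row counts (", base$n, " vs ",
         augmented$n, "); AIC values are not comparable")
  }
  if (base$convention != augmented$convention) {
    stop("models use different AIC conventions")
  }
  if (!all(base$predictors %in% augmented$predictors)) {
    stop("base predictors are not a subset of the augmented predictors")
  }
  structure(list(base = base, augmented = augmented,
                 delta_aic = base$aic - augmented$aic),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  added <- setdiff(x$augmented$predictors, x$base$predictors)
  cat(sprintf("<model_comparison> + %s: delta AIC = %.3f\n",
              paste(added, collapse = " + "), x$delta_aic))
  invisible(x)
}

#' Run the nested model-comparison ladder
#'
#' Fits the study's ladder of nested OLS models and returns each
#' comparison's AIC difference against its stated baseline:
#' \itemize{
#' \item `pnd_x_snd`: baseline vs baseline + PND x SND interaction;
#' \item `psc_te`, `psc_ld`: baseline vs baseline + each FSC measure;
#' \item `iconicity_psc_ld`: on the iconicity-complete subset, baseline +
#'   iconicity vs that model + PSC_ld;
#' \item `snd_x_psc_ld`: baseline + PSC_ld vs adding the SND x PSC_ld
#'   interaction.
#' }
#' Comparisons whose columns are absent are skipped, except that asking for
#' the iconicity branch without an iconicity column is an error.
#'
#' @param table study table with z-scored predictors.
#' @param response response column, default `"aoa"`.
#' @param baseline baseline predictor columns.
#' @param psc_te,psc_ld,iconicity,snd,pnd column names of the target
#'   measures (set to `NULL` to skip a branch).
#' @return list with `comparisons` (named `model_comparison` list) and
#'   `summary` (data.frame of added term, delta AIC, beta, se, t, p).
#' @export
run_nested_suite <- function(table, response = "aoa",
                             baseline = c("frequency", "concreteness",
                                          "length_phonemes", "valence",
                                          "morph_complex", "pnd", "snd"),
                             psc_te = "psc_te", psc_ld = "psc_ld",
                             iconicity = if ("iconicity" %in% names(table))
                               "iconicity" else NULL,
                             snd = "snd", pnd = "pnd") {
  base <- fit_linear(table, response, baseline)
  comparisons <- list()

  if (!is.null(pnd) && !is.null(snd)) {
    aug <- fit_linear(table, response, baseline,
                      interactions = list(c(pnd, snd)))
    comparisons$pnd_x_snd <- compare_models(base, aug)
  }
  for (m in c(psc_te, psc_ld)) {
    if (is.null(m)) next
    if (!m %in% names(table)) next
    aug <- fit_linear(table, response, c(baseline, m))
    comparisons[[m]] <- compare_models(base, aug)
  }
  if (!is.null(iconicity)) {
    if (!iconicity %in% names(table)) {
      stop("iconicity branch requested but no '", iconicity, "' column")
    }
    sub <- table[!is.na(table[[iconicity]]), , drop = FALSE]
    ibase <- fit_linear(sub, response, c(baseline, iconicity))
    iaug <- fit_linear(sub, response, c(baseline, iconicity, psc_ld))
    comparisons$iconicity_psc_ld <- compare_models(ibase, iaug)
  }
  if (!is.null(psc_ld) && psc_ld %in% names(table) && !is.null(snd)) {
    b2 <- fit_linear(table, response, c(baseline, psc_ld))
    aug <- fit_linear(table, response, c(baseline, psc_ld),
                      interactions = list(c(snd, psc_ld)))
    comparisons$snd_x_psc_ld <- compare_models(b2, aug)
  }

  summary <- do.call(rbind, lapply(names(comparisons), function(nm) {
    cmp <- comparisons[[nm]]
    added <- setdiff(cmp$augmented$predictors, cmp$base$predictors)
    ct <- cmp$augmented$coefficients
    row <- ct[rownames(ct) %in% c(added, gsub(":", ":", added)), , drop = FALSE]
    data.frame(comparison = nm, term = added,
               beta = row$beta[match(added, rownames(row))],
               se = row$se[match(added, rownames(row))],
               t = row$t[match(added, rownames(row))],
               p = row$p[match(added, rownames(row))],
               delta_aic = cmp$delta_aic, row.names = NULL)
  }))
  list(comparisons = comparisons, summary = summary)
}

#' Simple slopes of an FSC effect across SND quantiles
#'
#' For a fit containing the FSC main effect and the SND x FSC interaction,
#' the conditional slope at SND quantile q is
#' `beta_fsc + beta_interaction * snd_q`, with `snd_q` the q-th sample
#' quantile of the (z-scored) SND column.
#'
#' @param fit `model_fit` containing both terms.
#' @param data the data the model was fit to (source of the SND quantiles).
#' @param fsc,snd column names, defaults `"psc_ld"` and `"snd"`.
#' @param quantiles probabilities, default `c(0.05, 0.5, 0.95)` (dense,
#'   average, sparse semantic neighbourhoods).
#' @return data.frame with `quantile`, `snd_value`, `slope`.
#' @export
simple_slopes <- function(fit, data, fsc = "psc_ld", snd = "snd",
                          quantiles = c(0.05, 0.5, 0.95)) {
  ct <- fit$coefficients
  int_names <- c(paste0(snd, ":", fsc), paste0(fsc, ":", snd))
  int_row <- intersect(int_names, rownames(ct))
  if (!length(int_row)) {
    stop("fit contains no ", snd, " x ", fsc, " interaction term")
  }
  if (!fsc %in% rownames(ct)) stop("fit lacks the ", fsc, " main effect")
  b_fsc <- ct[fsc, "beta"]
  b_int <- ct[int_row[1L], "beta"]
  sq <- stats::quantile(data[[snd]], quantiles)
  data.frame(quantile = quantiles, snd_value = unname(sq),
             slope = b_fsc + b_int * unname(sq))
}

#' Pairwise Pearson correlation report
#'
#' Pearson r for every variable pair with a 95% confidence interval from
#' the Fisher z transform, the t statistic `r sqrt(df / (1 - r^2))` with
#' `df = n - 2`, and the two-sided p value. Pairs with fewer than 3
#' complete observations are flagged rather than dropped.
#'
#' @param table data.frame.
#' @param variables numeric columns to correlate.
#' @param conf confidence level, default 0.95.
#' @return data.frame with one row per unordered pair.
#' @export
correlation_report <- function(table, variables, conf = 0.95) {
  pairs <- utils::combn(variables, 2L)
  zq <- stats::qnorm(1 - (1 - conf) / 2)
  out <- lapply(seq_len(ncol(pairs)), function(j) {
    v1 <- pairs[1L, j]; v2 <- pairs[2L, j]
    x <- table[[v1]]; y <- table[[v2]]
    ok <- !is.na(x) & !is.na(y)
    n <- sum(ok)
    if (n < 3L) {
      return(data.frame(var1 = v1, var2 = v2, n = n, r = NA_real_,
                        ci_lower = NA_real_, ci_upper = NA_real_,
                        t = NA_real_, df = NA_integer_, p = NA_real_,
                        flagged = TRUE))
    }
    r <- stats::cor(x[ok], y[ok])
    z <- atanh(r); se <- 1 / sqrt(n - 3)
    df <- n - 2L
    tstat <- r * sqrt(df / (1 - r^2))
    data.frame(var1 = v1, var2 = v2, n = n, r = r,
               ci_lower = tanh(z - zq * se), ci_upper = tanh(z + zq * se),
               t = tstat, df = df,
               p = 2 * stats::pt(-abs(tstat), df), flagged = FALSE)
  })
  do.call(rbind, out)
}

#' Principal-component disentanglement of collinear measures
#'
#' Z-scores the (typically collinear) neighbourhood/systematicity measures,
#' eigendecomposes their correlation matrix into orthogonal components
#' (sign convention: each component's largest-magnitude loading is
#' positive), appends the per-word component scores, and regresses the
#' response on the components plus the control variables.
#'
#' @param table study table.
#' @param variables the measures to decompose, default
#'   `c("pnd", "snd", "psc_ld")`.
#' @param controls control predictor columns for the regression.
#' @param response response column, default `"aoa"`.
#' @return list with `pca` (`loadings`, `explained_variance`, `scores`)
#'   and `fit` (the `model_fit` on components + controls).
#' @export
pca_disentangle <- function(table, variables = c("pnd", "snd", "psc_ld"),
                            controls, response = "aoa") {
  Z <- scale(as.matrix(table[, variables, drop = FALSE]))
  C <- stats::cor(Z)
  e <- eigen(C, symmetric = TRUE)
  if (min(e$values) < 1e-10) stop("singular correlation matrix")
  L <- e$vectors
  for (j in seq_len(ncol(L))) {
    if (L[which.max(abs(L[, j])), j] < 0) L[, j] <- -L[, j]
  }
  pcs <- paste0("PC", seq_along(variables))
  dimnames(L) <- list(variables, pcs)
  scores <- Z %*% L
  tab <- table
  for (j in seq_along(pcs)) tab[[pcs[j]]] <- scores[, j]
  fit <- fit_linear(tab, response, c(pcs, controls))
  pca <- structure(list(loadings = L, explained_variance = e$values,
                        scores = scores), class = "pca_result")
  list(pca = pca, fit = fit)
}

#' @export
print.pca_result <- function(x, ...) {
  cat("<pca_result> explained variance:",
      paste(round(x$explained_variance, 3), collapse = ", "), "\n")
  print(round(x$loadings, 3))
  invisible(x)
}
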
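test_that("boxcox_z honours forced lambdas and its limit cases", {
  set.seed(51)
  tab <- data.frame(x = rlnorm(300), y = runif(300, 1, 9))

  forced1 <- boxcox_z(tab, "y", lambda = c(y = 1))
  expect_equal(cor(forced1$table$y, tab$y), 1, tolerance = 1e-12)
  expect_equal(mean(forced1$table$y), 0, tolerance = 1e-10)
  expect_equal(sd(forced1$table$y), 1, tolerance = 1e-10)

  forced0 <- boxcox_z(tab, "x", lambda = c(x = 0))
  shift <- max(0, 1e-6 - min(tab$x))
  expect_equal(forced0$table$x,
               as.vector(scale(log(tab$x + shift))), tolerance = 1e-10)

  expect_error(boxcox_z(data.frame(z = rep(2, 10)), "z"), "constant")
})

test_that("boxcox_z estimates lambda near 0 for log-normal data and agrees with MASS", {
  set.seed(52)
  tab <- data.frame(x = exp(rnorm(5000)))
  res <- boxcox_z(tab, "x")
  expect_lt(abs(res$spec$lambda), 0.1)

  # independent profile-likelihood oracle
  grid <- seq(-2, 2, by = 0.01)
  bc <- MASS::boxcox(tab$x ~ 1, lambda = grid, plotit = FALSE)
  expect_lt(abs(res$spec$lambda - bc$x[which.max(bc$y)]), 0.011)

  # spec reapplies exactly
  re <- apply_boxcox_z(res$spec, data.frame(x = tab$x))
  expect_equal(re$x, res$table$x, tolerance = 1e-12)
})

test_that("fit_linear recovers coefficients and validates the design", {
  set.seed(53)
  n <- 1000
  tab <- data.frame(x = rnorm(n))
  tab$y <- 2 * tab$x + rnorm(n, sd = 0.1)
  fit <- fit_linear(tab, "y", "x")
  expect_true(fit$coefficients["x", "beta"] > 1.9 &&
                fit$coefficients["x", "beta"] < 2.1)
  expect_identical(fit$n, as.integer(n))

  tab$x2 <- tab$x
  expect_error(fit_linear(tab, "y", c("x", "x2")), "aliased")
  tab$x3 <- NA_real_
  expect_error(fit_linear(tab, "y", "x3"), "missing values")
  expect_error(fit_linear(tab, "y", "nope"), "nope")
})

test_that("delta AIC is convention-invariant and matches the log-likelihood identity", {
  set.seed(54)
  n <- 400
  tab <- data.frame(a = rnorm(n), b = rnorm(n))
  tab$y <- 1 + 0.5 * tab$a - 0.3 * tab$b + rnorm(n)

  for (conv in c("loglik", "rss")) {
    base <- fit_linear(tab, "y", "a", aic_convention = conv)
    aug <- fit_linear(tab, "y", c("a", "b"), aic_convention = conv)
    cmp <- compare_models(base, aug)
    # independent identity: delta = 2*(ll_aug - ll_base) - 2*(k_aug - k_base)
    ll <- function(f) as.numeric(logLik(f$model))
    expect_equal(cmp$delta_aic, 2 * (ll(aug) - ll(base)) - 2, tolerance = 1e-8)
    if (conv == "loglik") d1 <- cmp$delta_aic else d2 <- cmp$delta_aic
  }
  expect_equal(d1, d2, tolerance = 1e-8)

  self <- fit_linear(tab, "y", "a")
  expect_equal(compare_models(self, self)$delta_aic, 0)
  expect_error(compare_models(fit_linear(tab, "y", c("a", "b")),
                              fit_linear(tab, "y", "a")), "subset")
  expect_error(compare_models(fit_linear(tab[1:100, ], "y", "a"),
                              fit_linear(tab, "y", c("a", "b"))),
               "row counts")
})

test_that("run_nested_suite builds the comparison ladder", {
  world <- build_synthetic_world(250, 0.7, seed = 55, vector_dim = 20)
  st <- world$study_z
  st$aoa <- generate_aoa(world$lexicon, st)$aoa
  suite <- run_nested_suite(st)
  expect_setequal(names(suite$comparisons),
                  c("pnd_x_snd", "psc_te", "psc_ld", "iconicity_psc_ld",
                    "snd_x_psc_ld"))
  for (cmp in suite$comparisons) {
    expect_identical(cmp$base$n, cmp$augmented$n)
    expect_true(all(cmp$base$predictors %in% cmp$augmented$predictors))
  }
  expect_identical(nrow(suite$summary), 5L)
  st$iconicity <- NULL
  expect_error(run_nested_suite(st, iconicity = "iconicity"), "iconicity")
})

test_that("simple_slopes evaluates the interaction algebra", {
  fake <- structure(list(coefficients = data.frame(
    beta = c(2, -0.7, 0.1, 0.165),
    row.names = c("(Intercept)", "psc_ld", "snd", "snd:psc_ld"))),
    class = "model_fit")
  dat <- data.frame(snd = seq(-2, 2, length.out = 101))
  sl <- simple_slopes(fake, dat, quantiles = c(0.05, 0.5, 0.9))
  expect_equal(sl$slope, -0.7 + 0.165 * sl$snd_value, tolerance = 1e-12)
  # hand value: beta_psc = -0.7, beta_int = 0.165 at snd_q = 1.6
  expect_equal(-0.7 + 0.165 * 1.6, -0.436, tolerance = 1e-12)

  # no moderation -> identical slopes everywhere
  flat <- fake
  flat$coefficients["snd:psc_ld", "beta"] <- 0
  expect_equal(unique(simple_slopes(flat, dat)$slope), -0.7)

  no_int <- structure(list(coefficients = data.frame(
    beta = c(1, -0.5), row.names = c("(Intercept)", "psc_ld"))),
    class = "model_fit")
  expect_error(simple_slopes(no_int, dat), "interaction")

  # end to end: fitted interaction model agrees with its own coefficients
  set.seed(56)
  n <- 500
  tab <- data.frame(psc_ld = rnorm(n), snd = rnorm(n), f = rnorm(n))
  tab$aoa <- 5 - 0.6 * tab$psc_ld + 0.2 * tab$snd +
    0.3 * tab$psc_ld * tab$snd + rnorm(n, sd = 0.3)
  fit <- fit_linear(tab, "aoa", c("psc_ld", "snd", "f"),
                    interactions = list(c("snd", "psc_ld")))
  sl2 <- simple_slopes(fit, tab)
  b <- fit$coefficients
  int_name <- intersect(c("snd:psc_ld", "psc_ld:snd"), rownames(b))
  expect_equal(sl2$slope,
               b["psc_ld", "beta"] + b[int_name, "beta"] * sl2$snd_value,
               tolerance = 1e-12)
})

test_that("correlation_report computes r, Fisher CI, t and df", {
  set.seed(57)
  n <- 1771
  # centred, exactly orthonormal columns (so the constructed r is exact)
  z <- qr.Q(qr(scale(cbind(rnorm(n), rnorm(n)), scale = FALSE)))
  r_target <- -0.059
  x <- z[, 1]
  y <- r_target * z[, 1] + sqrt(1 - r_target^2) * z[, 2]
  tab <- data.frame(x = x, y = y, neg = -x)
  rep <- correlation_report(tab, c("x", "y", "neg"))
  row <- rep[rep$var1 == "x" & rep$var2 == "y", ]
  expect_equal(row$r, r_target, tolerance = 1e-10)
  expect_identical(row$df, 1769L)
  # printed-precision agreement with t = -2.503 at r = -.059, df = 1769
  expect_lt(abs(row$t - (-2.503)), 0.05)
  expect_true(row$ci_lower < r_target && r_target < row$ci_upper)
  expect_equal(rep[rep$var1 == "x" & rep$var2 == "neg", "r"], -1,
               tolerance = 1e-12)

  tiny <- correlation_report(data.frame(a = c(1, 2, NA), b = c(NA, 1, 2)),
                             c("a", "b"))
  expect_true(tiny$flagged)
})

test_that("pca_disentangle conserves variance and matches a power-iteration oracle", {
  set.seed(58)
  n <- 600
  pnd <- rnorm(n)
  snd <- 0.6 * pnd + 0.8 * rnorm(n)
  psc <- -0.4 * pnd + 0.2 * snd + rnorm(n)
  ctrl <- rnorm(n)
  tab <- data.frame(pnd = pnd, snd = snd, psc_ld = psc, ctrl = ctrl)
  tab$aoa <- 3 + 0.5 * pnd - 0.7 * psc + rnorm(n)

  res <- pca_disentangle(tab, controls = "ctrl")
  expect_equal(sum(res$pca$explained_variance), 3, tolerance = 1e-10)
  expect_equal(crossprod(res$pca$loadings), diag(3), tolerance = 1e-10,
               ignore_attr = TRUE)

  # power-iteration oracle for the leading eigenvector
  C <- cor(scale(tab[, c("pnd", "snd", "psc_ld")]))
  v <- c(1, 1, 1)
  for (i in 1:500) { v <- C %*% v; v <- v / sqrt(sum(v^2)) }
  lead <- res$pca$loadings[, 1]
  if (sign(v[which.max(abs(v))]) < 0) v <- -v
  expect_equal(as.vector(v), unname(lead), tolerance = 1e-8)

  # isotropic case: shares all near 1/3
  iso <- data.frame(pnd = rnorm(2000), snd = rnorm(2000),
                    psc_ld = rnorm(2000), ctrl = rnorm(2000))
  iso$aoa <- rnorm(2000)
  shares <- pca_disentangle(iso, controls = "ctrl")$pca$explained_variance / 3
  expect_true(all(abs(shares - 1 / 3) < 0.05))

  dup <- tab
  dup$snd <- dup$pnd
  expect_error(pca_disentangle(dup, controls = "ctrl"), "singular")
})

test_that("rf_regression finds the informative predictor and predicts sensibly", {
  set.seed(59)
  n <- 600
  tab <- data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n),
                    x4 = rnorm(n), x5 = rnorm(n))
  tab$y <- 2 * tab$x1 + rnorm(n, sd = 0.5)
  fit <- rf_regression(tab, "y", paste0("x", 1:5), n_trees = 150, seed = 1)
  expect_identical(names(which.max(fit$importance)), "x1")
  expect_identical(fit$mtry, 1L)  # floor(5/3) = 1
  expect_gt(fit$oob_r2, 0.5)

  # OOB r2 close to r2 on an independent draw of the same process
  new <- data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n),
                    x4 = rnorm(n), x5 = rnorm(n))
  new$y <- 2 * new$x1 + rnorm(n, sd = 0.5)
  pred <- predict(fit, new)
  test_r2 <- 1 - mean((new$y - pred)^2) / var(new$y)
  expect_lt(abs(fit$oob_r2 - test_r2), 0.1)

  # pure-noise response: no skill
  noise <- tab
  noise$y <- rnorm(n)
  nf <- rf_regression(noise, "y", paste0("x", 1:5), n_trees = 150, seed = 2)
  expect_lt(nf$oob_r2, 0.05)

  expect_error(rf_regression(tab, "y", character()), "at least one")
  # seeded determinism
  f2 <- rf_regression(tab, "y", paste0("x", 1:5), n_trees = 50, seed = 7)
  f3 <- rf_regression(tab, "y", paste0("x", 1:5), n_trees = 50, seed = 7)
  expect_identical(f2$importance, f3$importance)
  expect_identical(f2$oob_pred, f3$oob_pred)
})
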
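# Exact GP inference: marginal likelihood, optimisation, prediction and the
# posterior decomposition.

test_that("the marginal likelihood matches its closed form at n = 1", {
  # noise-only model, sigma^2 = 1, y = 0: log density is -0.5 log(2 pi)
  nll_grad <- getFromNamespace("agp_nll_grad", "serogp")
  res <- nll_grad(log(1), list(), list(), logical(0), 0, 1e-8, 1e-4)
  expect_equal(-res$nll, -0.5 * log(2 * pi), tolerance = 1e-12)
})

test_that("the marginal likelihood agrees with a dense MVN oracle", {
  set.seed(7)
  for (rep in 1:25) {
    n <- sample(4:8, 1)
    df <- data.frame(y = rnorm(n), age = runif(n, 0, 36),
                     id = sample(c("a", "b"), n, replace = TRUE))
    hp <- list("age.variance" = runif(1, 0.05, 3),
               "age.lengthscale" = runif(1, 1, 40),
               "id.variance" = runif(1, 0.05, 3),
               "noise.variance" = runif(1, 0.05, 2))
    fit <- agp(y ~ age + id, df, optimize = FALSE, hyperparams = hp)
    X <- df[c("age", "id")]
    K <- build_kernel(kernel_spec("se_age", "age",
                                  variance = hp[["age.variance"]],
                                  lengthscale = hp[["age.lengthscale"]]), X) +
      build_kernel(kernel_spec("categorical", "id",
                               variance = hp[["id.variance"]]), X) +
      diag(hp[["noise.variance"]] + fit$jitter, n)
    y_std <- (df$y - mean(df$y)) / sd(df$y)
    expect_equal(fit$log_marginal, oracle_mvn_logdens(y_std, K),
                 tolerance = 1e-8)
  }
})

test_that("increasing the noise variance with y = 0 lowers the likelihood", {
  df <- data.frame(y = rep(0, 6), age = seq(3, 36, length.out = 6))
  lml <- function(nv) {
    # bypass response standardisation by evaluating the kernel path directly
    X <- df["age"]
    K <- build_kernel(kernel_spec("se_age", "age", variance = 1,
                                  lengthscale = 10), X) + diag(nv, 6)
    oracle_mvn_logdens(rep(0, 6), K)
  }
  vals <- vapply(c(0.5, 1, 2, 4), lml, numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("hyperparameter fitting is deterministic and recovers structure", {
  # same seed -> identical fit
  f1 <- toy_fit(seed = 3)
  f2 <- toy_fit(seed = 3)
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$log_marginal, f2$log_marginal)

  # stored log marginal likelihood equals recomputation
  expect_lt(abs(log_marginal_likelihood(f1) - f1$log_marginal), 1e-8)

  # pure white noise: signal variances shrink, noise soaks up the variance
  set.seed(11)
  df <- data.frame(y = rnorm(60), age = runif(60, 0, 36),
                   id = sample(letters[1:6], 60, replace = TRUE))
  fit <- agp(y ~ age + id, df, n_restarts = 3, seed = 1)
  co <- coef(fit)
  # standardised response: sample variance is 1 by construction
  expect_equal(unname(co["noise.variance"]), 1, tolerance = 0.25)
  expect_lt(unname(co["age.variance"]) , 0.2)

  # a drawn SE function is recovered with lengthscale within a factor of 2
  set.seed(5)
  x <- seq(0, 36, length.out = 80)
  K <- 2 * exp(-outer(x, x, "-")^2 / (2 * 8^2)) + diag(1e-8, 80)
  f <- drop(crossprod(chol(K), rnorm(80)))
  dfr <- data.frame(y = f + rnorm(80, 0, 0.2), age = x)
  fitr <- agp(y ~ age, dfr, n_restarts = 3, seed = 2)
  ell <- unname(coef(fitr)["age.lengthscale"])
  expect_gt(ell, 4)
  expect_lt(ell, 16)
})

test_that("failed optimisation carries per-restart diagnostics", {
  df <- data.frame(y = c(1, 2, 1), age = c(3, 6, 9))
  expect_error(agp(y ~ age, df), "at least 4")
  expect_error(agp(y ~ age, data.frame(y = rep(1, 6), age = 1:6)),
               "constant")
})

test_that("prediction follows the exact GP equations", {
  # n = 2 hand-computed solve
  df <- data.frame(y = c(1, -1), age = c(0, 10), extra = c(0, 0),
                   pad1 = 0, pad2 = 0)
  df <- rbind(df, data.frame(y = c(0.5, -0.5), age = c(2, 8), extra = 0,
                             pad1 = 0, pad2 = 0))
  hp <- list("age.variance" = 1, "age.lengthscale" = 5,
             "noise.variance" = 0.5)
  fit <- agp(y ~ age, df, optimize = FALSE, hyperparams = hp)
  Xq <- data.frame(age = 4)
  k <- exp(-outer(4, df$age, "-")^2 / 50)
  K <- exp(-outer(df$age, df$age, "-")^2 / 50) + diag(0.5 + fit$jitter, 4)
  y_std <- (df$y - mean(df$y)) / sd(df$y)
  mu_hand <- drop(k %*% solve(K, y_std)) * fit$y_sd + fit$y_mean
  pr <- predict(fit, Xq)
  expect_equal(pr$fit, mu_hand, tolerance = 1e-10)

  # interpolation limit: tiny noise pins the mean to the data
  hp0 <- list("age.variance" = 1, "age.lengthscale" = 5,
              "noise.variance" = 1e-6)
  fit0 <- agp(y ~ age, df, optimize = FALSE, hyperparams = hp0)
  pr0 <- predict(fit0, df["age"])
  expect_equal(pr0$fit, df$y, tolerance = 1e-3)

  # extrapolation limit: prior mean and full prior variance
  far <- predict(fit, data.frame(age = 1e4), include_noise = TRUE)
  expect_equal(far$fit, fit$y_mean, tolerance = 1e-8)
  expect_equal(far$se.fit, sqrt(1.5) * fit$y_sd, tolerance = 1e-6)
  expect_true(all(predict(fit, df["age"])$se.fit > 0))
})

test_that("posterior decomposition is additive with unit-sum shares", {
  fits <- list(toy_fit(seed = 1), toy_fit(seed = 2, formula =
    y ~ age + id + age:id + location),
    toy_fit(seed = 4, formula = y ~ age + season + gender + id))
  for (fit in fits) {
    co <- contributions(fit)
    expect_equal(co$total, predict(fit, se.fit = FALSE), tolerance = 1e-8)
    expect_equal(rowSums(co$contributions) + co$intercept, co$total,
                 tolerance = 1e-12)
    sh <- variance_shares(fit)
    expect_true(all(sh >= 0 & sh <= 1))
    expect_equal(sum(sh), 1, tolerance = 1e-8)
  }

  # single-component model: the component mean is the whole posterior mean
  df <- data.frame(y = rnorm(12, sin(1:12)), age = 1:12 * 3)
  fit1 <- agp(y ~ age, df, n_restarts = 2, seed = 1)
  co1 <- contributions(fit1)
  expect_equal(drop(co1$contributions[, "age"]) + co1$intercept,
               predict(fit1, se.fit = FALSE), tolerance = 1e-10)
})

test_that("a simulated location offset dominates the age share", {
  ann <- toy_annotation(n_subjects = 8, seed = 9)
  prot <- simulate_protein(ann, effect_config(location = 2, noise = 0.3),
                           seed = 9)
  df <- data.frame(y = prot$value, age = ann$age_months,
                   location = ann$location, id = ann$subject_id)
  fit <- agp(y ~ age + location + id, df, n_restarts = 3, seed = 1)
  sh <- variance_shares(fit)
  expect_gt(sh[["location"]], sh[["age"]])
})

test_that("posterior simulation is reproducible and respects dimensions", {
  fit <- toy_fit(seed = 6)
  s1 <- simulate(fit, nsim = 3, seed = 42)
  s2 <- simulate(fit, nsim = 3, seed = 42)
  expect_identical(s1, s2)
  expect_equal(dim(s1), c(fit$n, 3L))
  # residuals + fitted reconstruct the data
  expect_equal(fitted(fit) + residuals(fit), fit$y_obs)
})
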
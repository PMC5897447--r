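# S3 methods for "agp" fits.

#' @export
print.agp <- function(x, digits = 4, ...) {
  cat("Additive Gaussian process fit\n")
  cat("  call: ", deparse(x$call), "\n", sep = "")
  cat("  n = ", x$n, " observations, ", length(x$components),
      " signal component(s) + noise\n", sep = "")
  cat("  log marginal likelihood: ", format(x$log_marginal, digits = digits),
      " (standardised response)\n", sep = "")
  invisible(x)
}

#' @export
coef.agp <- function(object, ...) exp(object$par)

#' @export
logLik.agp <- function(object, ...) {
  structure(object$log_marginal, df = length(object$par), nobs = object$n,
            class = "logLik")
}

#' @export
summary.agp <- function(object, ...) {
  shares <- variance_shares(object)
  comp_tab <- data.frame(
    component = names(object$component_params),
    kind = vapply(object$components, `[[`, character(1), "kind"),
    variance = vapply(object$component_params, `[[`, numeric(1), "variance"),
    lengthscale = vapply(object$component_params, function(p)
      if (is.null(p$lengthscale)) NA_real_ else p$lengthscale, numeric(1)),
    share = unname(shares[names(object$component_params)]),
    row.names = NULL)
  structure(list(call = object$call, n = object$n,
                 components = comp_tab, noise_var = object$noise_var,
                 noise_share = unname(shares["noise"]),
                 log_marginal = object$log_marginal,
                 restarts = object$restarts, y_mean = object$y_mean,
                 y_sd = object$y_sd),
            class = "summary.agp")
}

#' @export
print.summary.agp <- function(x, digits = 4, ...) {
  cat("Additive Gaussian process fit\n")
  cat("  call: ", deparse(x$call), "\n", sep = "")
  cat("  n = ", x$n, "; response mean ", format(x$y_mean, digits = digits),
      ", sd ", format(x$y_sd, digits = digits), " (log2 scale)\n\n", sep = "")
  tab <- x$components
  tab$variance <- signif(tab$variance, digits)
  tab$lengthscale <- signif(tab$lengthscale, digits)
  tab$share <- signif(tab$share, digits)
  print(tab, row.names = FALSE)
  cat("  noise variance ", format(x$noise_var, digits = digits),
      " (share ", format(x$noise_share, digits = digits), ")\n", sep = "")
  cat("  log marginal likelihood ", format(x$log_marginal, digits = digits),
      "\n", sep = "")
  invisible(x)
}

#' Posterior prediction from an additive GP fit
#'
#' Standard exact GP predictive equations. Far from the training inputs the
#' mean reverts to the (response-scale) training mean and the variance to the
#' total signal variance plus, when `include_noise = TRUE`, the noise variance.
#'
#' @param object an [agp()] fit.
#' @param newdata data frame of covariates; defaults to the training inputs.
#'   Subjects (or other categorical levels) absent from the training data take
#'   zero cross-covariance for the corresponding components, so their
#'   individual terms contribute prior variance rather than a learned offset.
#' @param se.fit return predictive standard deviations as well.
#' @param include_noise add the noise variance to the predictive variance.
#' @param ... unused.
#' @return If `se.fit`, a list with components `fit` and `se.fit` (response
#'   scale); otherwise the vector of posterior means.
#' @export
predict.agp <- function(object, newdata = NULL, se.fit = TRUE,
                        include_noise = FALSE, ...) {
  newdata <- agp_check_newdata(object, newdata)
  Ks <- agp_cross(object, newdata)
  mean_std <- drop(Ks %*% object$alpha)
  fit <- mean_std * object$y_sd + object$y_mean
  if (!se.fit) return(fit)
  prior_var <- sum(vapply(object$component_params, `[[`, numeric(1),
                          "variance"))
  q <- rowSums((Ks %*% object$Kinv) * Ks)
  v <- pmax(prior_var - q, 0) + if (include_noise) object$noise_var else 0
  v <- pmax(v, 1e-12)
  list(fit = fit, se.fit = sqrt(v) * object$y_sd)
}

#' @export
fitted.agp <- function(object, ...) predict(object, se.fit = FALSE)

#' @export
residuals.agp <- function(object, ...) object$y_obs - fitted(object)

#' Draw from the posterior of an additive GP fit
#'
#' @param object an [agp()] fit.
#' @param nsim number of draws.
#' @param seed optional integer seed.
#' @param newdata covariates to simulate at (default: training inputs).
#' @param include_noise add observation noise to the draws.
#' @param ... unused.
#' @return A matrix with `nrow(newdata)` rows and `nsim` columns (response
#'   scale).
#' @export
simulate.agp <- function(object, nsim = 1, seed = NULL, newdata = NULL,
                         include_noise = TRUE, ...) {
  if (!is.null(seed)) set.seed(seed)
  newdata <- agp_check_newdata(object, newdata)
  m <- nrow(newdata)
  Ks <- agp_cross(object, newdata)
  mean_std <- drop(Ks %*% object$alpha)
  Kq <- matrix(0, m, m)
  for (i in seq_along(object$components)) {
    p <- object$component_params[[i]]
    Kq <- Kq + comp_cov(object$components[[i]], newdata, newdata, p$variance,
                        if (is.null(p$lengthscale)) 1 else p$lengthscale)
  }
  cov <- Kq - Ks %*% object$Kinv %*% t(Ks)
  if (include_noise) diag(cov) <- diag(cov) + object$noise_var
  diag(cov) <- diag(cov) + 1e-10
  L <- chol(cov)
  z <- matrix(rnorm(m * nsim), m, nsim)
  draws <- mean_std + crossprod(L, z)
  draws * object$y_sd + object$y_mean
}

#' Posterior mean contributions of the additive components
#'
#' Decomposes the posterior mean of an [agp()] fit into per-component
#' contribution functions, \eqn{m_c(x_*) = K_c(x_*, X)(K + \sigma^2 I)^{-1} y}.
#' The component contributions plus the intercept sum exactly to the full
#' posterior mean (additivity of the kernel).
#'
#' @param object an [agp()] fit.
#' @param newdata covariates to evaluate at (default: training inputs).
#' @param ... unused.
#' @return An object of class `"agp_contributions"`: a list with
#'   `contributions` (matrix, one column per component, response scale,
#'   centred), `intercept` (training mean), `total` (full posterior mean) and
#'   `shares` (see [variance_shares()]).
#' @export
contributions <- function(object, ...) UseMethod("contributions")

#' @rdname contributions
#' @export
contributions.agp <- function(object, newdata = NULL, ...) {
  newdata <- agp_check_newdata(object, newdata)
  m <- vapply(seq_along(object$components), function(i)
    drop(agp_cross(object, newdata, which = i) %*% object$alpha),
    numeric(nrow(newdata)))
  m <- matrix(m, nrow = nrow(newdata))
  colnames(m) <- names(object$component_params)
  m <- m * object$y_sd
  structure(list(contributions = m, intercept = object$y_mean,
                 total = rowSums(m) + object$y_mean,
                 shares = variance_shares(object)),
            class = "agp_contributions")
}

#' @export
print.agp_contributions <- function(x, digits = 4, ...) {
  cat("Additive GP posterior decomposition (", nrow(x$contributions),
      " inputs)\n", sep = "")
  cat("Variance shares:\n")
  print(signif(x$shares, digits))
  invisible(x)
}

#' Variance shares of the additive components
#'
#' The share of a component is the empirical variance of its posterior mean
#' contribution at the training inputs, normalised so that the component
#' shares plus the noise share (the fitted noise variance on the standardised
#' scale) sum to one. This is the quantity used to rank, e.g., individual
#' against age-associated variation for a protein.
#'
#' @param object an [agp()] fit.
#' @return A named vector of shares in `[0, 1]` (components plus `"noise"`),
#'   summing to 1.
#' @export
variance_shares <- function(object) {
  stopifnot(inherits(object, "agp"))
  v <- vapply(seq_along(object$components), function(i) {
    m <- drop(agp_cross(object, object$X, which = i) %*% object$alpha)
    var(m)
  }, numeric(1))
  names(v) <- names(object$component_params)
  tot <- c(v, noise = object$noise_var)
  tot / sum(tot)
}

#' Plot an additive GP fit against one covariate
#'
#' Plots the observations against `covariate` together with the
#' population-level posterior mean (individual-specific components averaged
#' out by predicting for an unseen subject) and a 95% band.
#'
#' @param x an [agp()] fit.
#' @param covariate name of a numeric covariate (default `"age"`).
#' @param n_grid grid resolution.
#' @param ... passed to [plot()].
#' @return Invisibly, the grid data frame with `fit` and `se.fit`.
#' @export
plot.agp <- function(x, covariate = "age", n_grid = 100, ...) {
  if (!covariate %in% colnames(x$X) || !is.numeric(x$X[[covariate]]))
    stop("'", covariate, "' is not a numeric covariate of this fit")
  grid <- x$X[rep(1L, n_grid), , drop = FALSE]
  grid[[covariate]] <- seq(min(x$X[[covariate]]), max(x$X[[covariate]]),
                           length.out = n_grid)
  for (v in colnames(grid)) {
    if (!is.numeric(grid[[v]])) {
      # an unseen level: categorical components revert to their prior mean 0
      grid[[v]] <- rep("..population..", n_grid)
    } else if (v != covariate) {
      grid[[v]] <- mean(x$X[[v]])
    }
  }
  pr <- predict(x, grid)
  ord <- order(grid[[covariate]])
  xx <- grid[[covariate]][ord]
  plot(x$X[[covariate]], x$y_obs, xlab = covariate, ylab = "log2 intensity",
       ...)
  polygon(c(xx, rev(xx)),
          c(pr$fit[ord] + 1.96 * pr$se.fit[ord],
            rev(pr$fit[ord] - 1.96 * pr$se.fit[ord])),
          col = grey(0.85), border = NA)
  points(x$X[[covariate]], x$y_obs)
  lines(xx, pr$fit[ord], lwd = 2)
  invisible(data.frame(grid, fit = pr$fit, se.fit = pr$se.fit))
}
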
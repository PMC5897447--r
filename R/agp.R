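# Additive Gaussian process regression for longitudinal protein profiles.

term_component <- function(label, X, periodic, period) {
  vars <- strsplit(label, ":", fixed = TRUE)[[1L]]
  if (length(vars) == 1L) {
    x <- X[[vars]]
    if (is.numeric(x)) {
      if (vars %in% periodic) return(agp_component("per", vars, period = period))
      return(agp_component("se", vars))
    }
    return(agp_component("cat", vars))
  }
  if (length(vars) == 2L) {
    num <- vars[vapply(vars, function(v) is.numeric(X[[v]]), logical(1))]
    cat <- setdiff(vars, num)
    if (length(num) == 1L && length(cat) == 1L && !(num %in% periodic))
      return(agp_component("prod", list(num, cat), label = label))
  }
  stop("unsupported model term '", label,
       "': interactions must pair one numeric and one categorical covariate")
}

# Assemble the log-scale parameter vector layout, bounds and random inits.
par_layout <- function(comps, lengthscale_bounds, variance_bounds) {
  nm <- character(0)
  lower <- numeric(0)
  upper <- numeric(0)
  for (comp in comps) {
    nm <- c(nm, paste0(comp$label, ".variance"))
    lower <- c(lower, log(variance_bounds[1L]))
    upper <- c(upper, log(variance_bounds[2L]))
    if (comp_has_ls(comp)) {
      nm <- c(nm, paste0(comp$label, ".lengthscale"))
      lower <- c(lower, log(lengthscale_bounds[1L]))
      upper <- c(upper, log(lengthscale_bounds[2L]))
    }
  }
  nm <- c(nm, "noise.variance")
  lower <- c(lower, log(variance_bounds[1L]))
  upper <- c(upper, log(variance_bounds[2L]))
  list(names = nm, lower = lower, upper = upper)
}

random_inits <- function(comps, n_restarts, lay) {
  inits <- matrix(NA_real_, n_restarts, length(lay$names))
  for (r in seq_len(n_restarts)) {
    p <- numeric(0)
    for (comp in comps) {
      p <- c(p, runif(1, log(0.05), log(1)))
      if (comp_has_ls(comp)) {
        rng <- if (comp$kind == "per") log(c(0.5, 4)) else log(c(3, 30))
        p <- c(p, runif(1, rng[1L], rng[2L]))
      }
    }
    p <- c(p, runif(1, log(0.05), log(1)))
    inits[r, ] <- pmin(pmax(p, lay$lower), lay$upper)
  }
  inits
}

#' Fit an additive Gaussian process to a longitudinal protein profile
#'
#' Models a (log2) protein expression trajectory as a sum of Gaussian process
#' components, one per covariate term in the model formula, plus white noise.
#' Numeric covariates get a squared-exponential kernel (or a periodic kernel
#' with period `period` when listed in `periodic`); categorical covariates get
#' a block-constant kernel; an interaction such as `age:id` gets the product of
#' an SE kernel on age and the subject indicator, giving each subject its own
#' smooth deviation. The response is standardised internally (mean 0, sd 1 over
#' the non-missing values) and all hyperparameters, including the noise
#' variance, are estimated on that scale by type-II maximum likelihood with
#' multi-restart L-BFGS-B; predictions are reported back on the response scale.
#'
#' Rows with missing response or covariates are dropped (never imputed).
#'
#' @param formula model formula, e.g. `y ~ age + id + age:id + location`.
#' @param data data frame with the response and covariate columns.
#' @param periodic names of numeric covariates modelled with the periodic
#'   kernel (default `"season"`).
#' @param period period of the seasonal kernel in months.
#' @param n_restarts number of random optimiser restarts.
#' @param seed integer seed controlling the restart draws.
#' @param lengthscale_bounds,variance_bounds box constraints for the
#'   hyperparameters (lengthscales in months; variances on the standardised
#'   response scale, bounds applying to signal and noise variances alike).
#' @param jitter initial diagonal jitter used if the Cholesky factorisation
#'   fails; escalated tenfold up to `1e-4` before giving up.
#' @param hyperparams optional named list of fixed hyperparameters (natural
#'   scale), e.g. `list("age.variance" = 1, "age.lengthscale" = 10,
#'   "noise.variance" = 0.5)`. When supplied with `optimize = FALSE` the model
#'   is evaluated at these values without fitting.
#' @param optimize logical; optimise the hyperparameters (default) or evaluate
#'   at `hyperparams`.
#' @param init optional list of additional start vectors (log scale, full
#'   parameter layout) appended to the random restarts.
#' @param control passed to [stats::optim()].
#' @return An object of class `"agp"` with components including the fitted
#'   kernel hyperparameters, the log marginal likelihood, and cached solves
#'   used by [predict.agp()], [contributions()], [loocv_mlpd()] and
#'   [scv_mlpd()].
#' @examples
#' ann <- simulate_design(study_design(n_subjects = 6), seed = 1)
#' ann <- ann[!ann$is_cord, ]
#' prot <- simulate_protein(ann, effect_config(age = 1), seed = 2)
#' df <- data.frame(y = prot$value, age = ann$age_months, id = ann$subject_id)
#' fit <- agp(y ~ age + id + age:id, df, n_restarts = 2, seed = 1)
#' fit
#' @seealso [predict.agp()], [contributions()], [variance_shares()],
#'   [loocv_mlpd()], [scv_mlpd()], [select_effects()]
#' @export
agp <- function(formula, data, periodic = "season", period = 12,
                n_restarts = 5, seed = 1,
                lengthscale_bounds = c(0.5, 100),
                variance_bounds = c(1e-6, 10),
                jitter = 1e-8, hyperparams = NULL,
                optimize = is.null(hyperparams),
                init = NULL, control = list(maxit = 200)) {
  cl <- match.call()
  mf <- model.frame(formula, data, na.action = na.pass)
  y_raw <- model.response(mf)
  if (!is.numeric(y_raw)) stop("the response must be numeric")
  tl <- attr(terms(mf), "term.labels")
  if (!length(tl)) stop("the model formula needs at least one covariate term")
  vars <- unique(unlist(strsplit(tl, ":", fixed = TRUE)))
  X <- mf[vars]
  keep <- complete.cases(X) & is.finite(y_raw)
  X <- X[keep, , drop = FALSE]
  y_raw <- y_raw[keep]
  n <- length(y_raw)
  if (n < 4L) stop("need at least 4 non-missing observations, got ", n)

  comps <- lapply(tl, function(lab)
    term_component(lab, X, periodic = periodic, period = period))
  y_mean <- mean(y_raw)
  y_sd <- sd(y_raw)
  if (!is.finite(y_sd) || y_sd == 0)
    stop("the response is constant; nothing to model")
  y <- (y_raw - y_mean) / y_sd

  structs <- lapply(comps, comp_struct, X1 = X, X2 = X)
  Qs <- lapply(structs, `[[`, "Q")
  Ms <- lapply(structs, `[[`, "M")
  has_ls <- vapply(comps, comp_has_ls, logical(1))
  lay <- par_layout(comps, lengthscale_bounds, variance_bounds)
  npar <- length(lay$names)

  # objective with a one-step cache so optim's fn/gr pairs cost one C++ call
  cache <- new.env(parent = emptyenv())
  evaluate <- function(p) {
    if (!is.null(cache$par) && identical(p, cache$par)) return(cache$res)
    res <- agp_nll_grad(p, Qs, Ms, has_ls, y, jitter, 1e-4)
    cache$par <- p
    cache$res <- res
    res
  }
  fn <- function(p) evaluate(p)$nll
  gr <- function(p) evaluate(p)$grad

  par_from_list <- function(hp) {
    p <- setNames(rep(NA_real_, npar), lay$names)
    unknown <- setdiff(names(hp), lay$names)
    if (length(unknown))
      stop("unknown hyperparameter(s): ", paste(unknown, collapse = ", "))
    p[names(hp)] <- log(unlist(hp))
    if (anyNA(p))
      stop("hyperparameters missing for: ",
           paste(lay$names[is.na(p)], collapse = ", "))
    unname(p)
  }

  if (!optimize) {
    if (is.null(hyperparams))
      stop("'hyperparams' must be given when optimize = FALSE")
    best_par <- par_from_list(hyperparams)
    restart_log <- data.frame(restart = 0L, value = fn(best_par),
                              convergence = 0L)
  } else {
    set.seed(seed)
    inits <- random_inits(comps, n_restarts, lay)
    if (!is.null(hyperparams)) inits <- rbind(inits, par_from_list(hyperparams))
    if (!is.null(init))
      inits <- rbind(inits, do.call(rbind, lapply(init, function(p)
        pmin(pmax(p, lay$lower), lay$upper))))
    fits <- vector("list", nrow(inits))
    for (r in seq_len(nrow(inits))) {
      fits[[r]] <- tryCatch(
        optim(inits[r, ], fn, gr, method = "L-BFGS-B",
              lower = lay$lower, upper = lay$upper, control = control),
        error = function(e) list(value = Inf, convergence = 99L,
                                 message = conditionMessage(e)))
    }
    vals <- vapply(fits, function(f) f$value, numeric(1))
    restart_log <- data.frame(
      restart = seq_along(fits), value = vals,
      convergence = vapply(fits, function(f) as.integer(f$convergence),
                           integer(1)))
    if (all(!is.finite(vals)) || min(vals) >= 1e10) {
      stop("no optimiser restart converged to a usable optimum; diagnostics:\n",
           paste(utils::capture.output(print(restart_log)), collapse = "\n"))
    }
    best_par <- fits[[which.min(vals)]]$par
  }

  final <- evaluate(best_par)
  if (!isTRUE(final$ok))
    stop("Cholesky factorisation failed even after jitter escalation to 1e-4")
  jitter_used <- final$jitter

  # cache solves at the optimum for prediction, CV and decomposition
  params <- setNames(exp(best_par), lay$names)
  noise_var <- unname(params["noise.variance"])
  K_signal <- matrix(0, n, n)
  comp_pars <- vector("list", length(comps))
  for (i in seq_along(comps)) {
    v <- unname(params[paste0(comps[[i]]$label, ".variance")])
    l <- if (has_ls[i]) unname(params[paste0(comps[[i]]$label, ".lengthscale")]) else 1
    comp_pars[[i]] <- list(variance = v, lengthscale = if (has_ls[i]) l else NULL)
    K_signal <- K_signal + comp_cov(comps[[i]], X, X, v, l)
  }
  K <- K_signal
  diag(K) <- diag(K) + noise_var + jitter_used
  ch <- chol(K)
  Kinv <- chol2inv(ch)
  alpha <- drop(Kinv %*% y)

  structure(list(
    call = cl, formula = formula, terms = tl,
    components = comps, component_params = setNames(comp_pars,
      vapply(comps, `[[`, character(1), "label")),
    par = setNames(best_par, lay$names), par_names = lay$names,
    noise_var = noise_var,
    X = X, y_std = y, y_obs = y_raw, y_mean = y_mean, y_sd = y_sd, n = n,
    log_marginal = -final$nll, jitter = jitter_used,
    K_signal = K_signal, Kinv = Kinv, alpha = alpha,
    periodic = periodic, period = period,
    bounds = list(lengthscale = lengthscale_bounds,
                  variance = variance_bounds),
    seed = seed, n_restarts = n_restarts, restarts = restart_log,
    optimized = optimize,
    struct = list(Q = Qs, M = Ms, has_ls = has_ls, jitter0 = jitter)),
    class = "agp")
}

#' Log marginal likelihood of a fitted additive GP
#'
#' Recomputes \eqn{\log N(y \mid 0, K + \sigma^2 I)} from the stored
#' hyperparameters of an [agp()] fit (standardised response scale). The stored
#' `log_marginal` equals this recomputation to within 1e-8.
#'
#' @param object an `"agp"` fit.
#' @param ... unused.
#' @return A single number, the log marginal likelihood.
#' @export
log_marginal_likelihood <- function(object, ...) {
  stopifnot(inherits(object, "agp"))
  res <- agp_nll_grad(unname(object$par), object$struct$Q, object$struct$M,
                      object$struct$has_ls, object$y_std,
                      object$struct$jitter0, 1e-4)
  if (!isTRUE(res$ok)) stop("Cholesky factorisation failed on recomputation")
  -res$nll
}

# Cross-covariance (signal only) between new inputs and the training inputs,
# optionally restricted to a subset of components.
agp_cross <- function(object, newdata, which = seq_along(object$components)) {
  K <- matrix(0, nrow(newdata), object$n)
  for (i in which) {
    comp <- object$components[[i]]
    p <- object$component_params[[i]]
    K <- K + comp_cov(comp, newdata, object$X, p$variance,
                      if (is.null(p$lengthscale)) 1 else p$lengthscale)
  }
  K
}

agp_check_newdata <- function(object, newdata) {
  if (is.null(newdata)) return(object$X)
  newdata <- as.data.frame(newdata)
  missing_vars <- setdiff(colnames(object$X), colnames(newdata))
  if (length(missing_vars))
    stop("newdata lacks covariate column(s): ",
         paste(missing_vars, collapse = ", "))
  newdata
}
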
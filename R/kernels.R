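# Kernel components for the additive GP.
#
# Internal representation: a component is a list(kind, vars, period, label)
# with kind one of
#   "se"   squared exponential on one numeric covariate (age),
#   "per"  periodic on one numeric covariate (month-of-year, period 12),
#   "cat"  block-constant on one categorical covariate (gender/location/id),
#   "prod" product of an SE factor and a categorical factor (age x id).
# Each component covariance can be written K = v * M * exp(-Q / ell^2) with a
# fixed distance matrix Q (NULL for "cat") and 0/1 mask M (NULL for "se"/"per"),
# which is the form the compiled likelihood consumes.

agp_component <- function(kind, vars, period = 12, label = NULL) {
  kind <- match.arg(kind, c("se", "per", "cat", "prod"))
  if (is.null(label)) label <- paste(vars, collapse = ":")
  structure(list(kind = kind, vars = vars, period = period, label = label),
            class = "agp_component")
}

comp_has_ls <- function(comp) comp$kind %in% c("se", "per", "prod")

# Fixed Q/M structure of a component between two covariate tables.
comp_struct <- function(comp, X1, X2 = X1) {
  Q <- NULL
  M <- NULL
  if (comp$kind %in% c("se", "prod")) {
    v <- if (comp$kind == "prod") comp$vars[[1L]] else comp$vars
    d <- outer(X1[[v]], X2[[v]], "-")
    Q <- d^2 / 2
  } else if (comp$kind == "per") {
    d <- outer(X1[[comp$vars]], X2[[comp$vars]], "-")
    Q <- 2 * sin(pi * d / comp$period)^2
  }
  if (comp$kind %in% c("cat", "prod")) {
    v <- if (comp$kind == "prod") comp$vars[[2L]] else comp$vars
    M <- outer(as.character(X1[[v]]), as.character(X2[[v]]), "==") + 0
  }
  list(Q = Q, M = M)
}

# Covariance matrix of one component at given hyperparameters.
comp_cov <- function(comp, X1, X2 = X1, variance = 1, lengthscale = 1) {
  s <- comp_struct(comp, X1, X2)
  K <- matrix(variance, nrow(X1), nrow(X2))
  if (!is.null(s$Q)) K <- K * exp(-s$Q / lengthscale^2)
  if (!is.null(s$M)) K <- K * s$M
  K
}

#' Specify a single kernel component
#'
#' Constructs the specification of one additive covariance component of the
#' longitudinal model. The kernel menu is fixed to the forms used throughout
#' the package: squared exponential for age, block-constant (categorical) for
#' gender/location/subject, a periodic kernel with a 12-month period for
#' sampling season, a product of an SE and a categorical factor for the
#' age-by-subject interaction, and white noise.
#'
#' @param kind one of `"se_age"`, `"categorical"`, `"periodic_season"`,
#'   `"product"`, `"noise"`.
#' @param covariates character vector of covariate (column) names the kernel
#'   references. Products need at least two distinct covariates, the first
#'   numeric (SE factor) and the second categorical; `"noise"` takes none.
#' @param variance signal variance \eqn{v \ge 0}.
#' @param lengthscale lengthscale \eqn{\ell > 0}; required for `"se_age"`,
#'   `"periodic_season"` and `"product"`.
#' @param period period of the seasonal kernel in months (fixed default 12).
#' @return An object of class `"kernel_spec"`.
#' @examples
#' ks <- kernel_spec("se_age", "age", variance = 1, lengthscale = 10)
#' X <- data.frame(age = c(3, 6, 12))
#' build_kernel(ks, X)
#' @export
kernel_spec <- function(kind = c("se_age", "categorical", "periodic_season",
                                 "product", "noise"),
                        covariates = character(), variance = 1,
                        lengthscale = NULL, period = 12) {
  kind <- match.arg(kind)
  if (!is.numeric(variance) || length(variance) != 1L || variance < 0)
    stop("'variance' must be a single nonnegative number")
  if (kind != "noise" && length(covariates) < 1L)
    stop("kernel '", kind, "' must reference at least one covariate")
  if (kind == "product" && length(unique(covariates)) < 2L)
    stop("product kernels must reference at least two distinct covariates")
  if (kind %in% c("se_age", "periodic_season", "product")) {
    if (is.null(lengthscale) || !is.numeric(lengthscale) || lengthscale <= 0)
      stop("kernel '", kind, "' needs a positive lengthscale")
  }
  structure(list(kind = kind, covariates = covariates, variance = variance,
                 lengthscale = lengthscale, period = period),
            class = "kernel_spec")
}

kernel_spec_component <- function(spec) {
  switch(spec$kind,
    se_age = agp_component("se", spec$covariates[[1L]]),
    categorical = agp_component("cat", spec$covariates[[1L]]),
    periodic_season = agp_component("per", spec$covariates[[1L]],
                                    period = spec$period),
    product = agp_component("prod", as.list(spec$covariates[1:2])),
    stop("no plain component for kind '", spec$kind, "'"))
}

#' Build a kernel covariance matrix
#'
#' Evaluates the covariance matrix of a [kernel_spec()] between two sets of
#' inputs. On identical inputs the result is symmetric positive semi-definite.
#' The noise kernel is defined on identical inputs only, where it contributes
#' `variance` times the identity.
#'
#' @param spec a [kernel_spec()].
#' @param X1,X2 data frames holding the covariate columns the spec references.
#'   `X2` defaults to `X1`.
#' @return A `nrow(X1)` by `nrow(X2)` covariance matrix.
#' @export
build_kernel <- function(spec, X1, X2 = X1) {
  stopifnot(inherits(spec, "kernel_spec"))
  X1 <- as.data.frame(X1)
  X2 <- as.data.frame(X2)
  if (spec$kind == "noise") {
    if (!identical(dim(X1), dim(X2)) || !isTRUE(all.equal(X1, X2,
                                                          check.attributes = FALSE)))
      stop("the noise kernel is defined only for X1 = X2")
    return(diag(spec$variance, nrow(X1)))
  }
  comp <- kernel_spec_component(spec)
  missing_vars <- setdiff(unlist(comp$vars), colnames(X1))
  if (length(missing_vars))
    stop("covariate column(s) missing from inputs: ",
         paste(missing_vars, collapse = ", "))
  ls <- if (is.null(spec$lengthscale)) 1 else spec$lengthscale
  comp_cov(comp, X1, X2, variance = spec$variance, lengthscale = ls)
}
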
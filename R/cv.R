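# Cross-validated predictive densities for additive GP fits.
#
# Both scores are computed on the standardised response scale with the
# hyperparameters held fixed at their full-data optima, so scores are directly
# comparable across the candidate models of one protein.

#' Leave-one-out mean log predictive density (closed form)
#'
#' Computes the exact leave-one-out predictive density of every observation
#' under a fitted additive GP, using the closed-form identities
#' \eqn{\mu_{-i} = y_i - [K^{-1} y]_i / [K^{-1}]_{ii}} and
#' \eqn{\sigma^2_{-i} = 1 / [K^{-1}]_{ii}} (with \eqn{K} including the noise
#' variance), and returns their mean log value. Hyperparameters are held fixed
#' across folds; the result is identical to explicitly refitting the posterior
#' n times at those hyperparameters. LOOCV scores time-varying covariates
#' (age, season): held-out single observations are predicted from the
#' remaining observations of the same and other subjects.
#'
#' @param fit an [agp()] fit.
#' @return The mean log predictive density (standardised response scale).
#' @export
loocv_mlpd <- function(fit) {
  stopifnot(inherits(fit, "agp"))
  d <- diag(fit$Kinv)
  mu <- fit$y_std - fit$alpha / d
  s2 <- 1 / d
  mean(dnorm(fit$y_std, mu, sqrt(s2), log = TRUE))
}

# Stratified fold assignment: subjects are grouped by their level of the
# tested covariate and dealt round-robin into folds, so every fold mixes
# levels as evenly as the design allows.
stratified_subject_folds <- function(subjects, levels_by_subject, n_folds,
                                     seed) {
  set.seed(seed)
  folds <- vector("list", n_folds)
  for (lev in unique(levels_by_subject)) {
    subj <- sample(subjects[levels_by_subject == lev])
    for (i in seq_along(subj)) {
      k <- ((i - 1L) %% n_folds) + 1L
      folds[[k]] <- c(folds[[k]], subj[i])
    }
  }
  folds[lengths(folds) > 0L]
}

#' Stratified subject-level cross-validated mean log predictive density
#'
#' Scores an additive GP by holding out entire subjects, so that
#' subject-constant covariates (gender, living environment) must generalise to
#' unseen individuals: the held-out subject's individual component contributes
#' its prior variance rather than a learned offset (its cross-covariance with
#' the training subjects is zero under the categorical subject kernel). Folds
#' are leave-one-subject-out by default; with more than 20 subjects a
#' stratified k-fold split over subjects is used, balancing the levels of the
#' covariate under test across folds. Hyperparameters are held fixed at their
#' full-data optima.
#'
#' @param fit an [agp()] fit whose covariates include the subject identifier
#'   column `subject_col`.
#' @param covariate optional name of the subject-constant covariate under
#'   test; each of its levels must be carried by at least two subjects.
#' @param n_folds number of folds when k-fold is used (default 10).
#' @param seed seed controlling the stratified fold assignment (unused for
#'   leave-one-subject-out, which is deterministic).
#' @param subject_col name of the subject identifier column (default `"id"`).
#' @return The mean log predictive density over all held-out observations
#'   (standardised response scale).
#' @export
scv_mlpd <- function(fit, covariate = NULL, n_folds = 10, seed = 1,
                     subject_col = "id") {
  stopifnot(inherits(fit, "agp"))
  if (!subject_col %in% colnames(fit$X))
    stop("fit has no '", subject_col, "' covariate; subject-level CV needs one")
  subj <- as.character(fit$X[[subject_col]])
  subjects <- unique(subj)
  if (!is.null(covariate)) {
    if (!covariate %in% colnames(fit$X))
      stop("fit has no '", covariate, "' covariate")
    lev_by_subj <- vapply(subjects, function(s)
      as.character(fit$X[[covariate]][subj == s][1L]), character(1))
    bad <- names(which(table(lev_by_subj) < 2L))
    if (length(bad))
      stop("covariate '", covariate, "' level(s) with a single subject (",
           paste(bad, collapse = ", "),
           "): effect unidentifiable under subject-level CV")
  }
  if (length(subjects) > 20L && !is.null(covariate)) {
    folds <- stratified_subject_folds(subjects,
                                      lev_by_subj[subjects], n_folds, seed)
  } else if (length(subjects) > 20L) {
    folds <- stratified_subject_folds(subjects,
                                      rep("all", length(subjects)),
                                      n_folds, seed)
  } else {
    folds <- as.list(subjects)
  }

  Ksig <- fit$K_signal
  nv <- fit$noise_var + fit$jitter
  lpd <- numeric(0)
  for (fold in folds) {
    S <- which(subj %in% fold)
    T <- which(!subj %in% fold)
    KTT <- Ksig[T, T, drop = FALSE]
    diag(KTT) <- diag(KTT) + nv
    cross <- Ksig[S, T, drop = FALSE]
    Kinv_T <- chol2inv(chol(KTT))
    w <- cross %*% Kinv_T
    mu <- drop(w %*% fit$y_std[T])
    v <- diag(Ksig)[S] + nv - rowSums(w * cross)
    v <- pmax(v, 1e-12)
    lpd <- c(lpd, dnorm(fit$y_std[S], mu, sqrt(v), log = TRUE))
  }
  mean(lpd)
}
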
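# Rank-based cross-comparison of cord-blood and follow-up proteomes.

#' Within-sample intensity ranks
#'
#' Ranks proteins within each sample by descending intensity (1 = most
#' abundant), averaging ties; missing entries stay missing. Ranks are
#' invariant to any strictly monotone transform of the intensities, which is
#' what makes them comparable across separately processed batches.
#'
#' @param x a proteins x samples matrix or an [expression_set()].
#' @return A matrix of within-sample ranks with the same dimnames.
#' @export
intensity_ranks <- function(x) {
  values <- if (inherits(x, "expression_set")) x$values else x
  out <- apply(values, 2L, function(v)
    rank(-v, na.last = "keep", ties.method = "average"))
  dimnames(out) <- dimnames(values)
  out
}

# Expected number of null rank products <= each threshold, per permutation.
# Under exchangeability one protein's per-pair ranks are independent uniforms
# on 1..m, so the expectation can be enumerated exactly over the m^k grid.
rp_expected_exact <- function(thresholds, m, k) {
  grid <- as.matrix(expand.grid(rep(list(seq_len(m)), k)))
  log_rp <- rowSums(log(grid)) / k
  vapply(thresholds, function(t)
    m * mean(log_rp <= log(t) + 1e-9), numeric(1))
}

rp_expected_perm <- function(thresholds, m, k, B) {
  log_null <- matrix(0, m, B)
  for (j in seq_len(k)) {
    perms <- matrix(0L, m, B)
    for (b in seq_len(B)) perms[, b] <- sample.int(m)
    log_null <- log_null + log(perms)
  }
  log_null <- sort(as.vector(log_null)) / k
  vapply(thresholds, function(t)
    findInterval(log(t) + 1e-9, log_null) / B, numeric(1))
}

#' Paired rank product test between cord-blood and follow-up samples
#'
#' For each paired subject, proteins are ranked by the within-pair difference
#' of their (log2 or rank-scale) values; the rank product of a protein is the
#' geometric mean of its per-pair ranks. Small rank products in the "up"
#' direction indicate consistently higher relative expression in cord blood
#' (and conversely for "down"). Significance is assessed by the percentage of
#' false prediction (pfp): the expected number of null proteins at least as
#' extreme, estimated under the exchangeable null by `B` independent
#' permutations of the within-pair ranks (or exact enumeration for tiny
#' problems), divided by the observed number of proteins at least as extreme.
#' pfp values are made monotone non-decreasing in rank-product order by a
#' reverse cumulative minimum.
#'
#' @param cord_matrix,followup_matrix proteins x subjects matrices with
#'   matching row names and subject column names (e.g. cord values and
#'   3-month values). Subjects without a column in both matrices are excluded
#'   with a warning. Missing values are allowed: each pair ranks only the
#'   proteins observed in that pair, a protein's rank product is the geometric
#'   mean over its observed pairs, and the permutation null preserves the
#'   missingness pattern; proteins observed in fewer than `min_pairs` pairs
#'   are dropped with a warning.
#' @param pairs optional character vector of subject ids to use.
#' @param B number of permutations (default 10000; below 1000 a warning is
#'   issued). Ignored when the data are complete and the exact enumeration is
#'   feasible (`m^k <= max_exact`).
#' @param seed integer seed for the permutations.
#' @param pfp_threshold significance threshold on pfp (default 0.05).
#' @param max_exact maximum `m^k` grid size for exact enumeration.
#' @param min_pairs minimum number of observed pairs per protein (default 2).
#' @return A data frame with one row per protein: `rp_up`, `pfp_up`,
#'   `rp_down`, `pfp_down`, `direction` (`"up"` = higher in cord blood) and
#'   `significant` (minimum-direction pfp below `pfp_threshold`). Attributes
#'   `method` (`"exact"`/`"permutation"`), `B`, `seed` and `n_pairs` record
#'   the null computation.
#' @export
rank_product_test <- function(cord_matrix, followup_matrix, pairs = NULL,
                              B = 10000, seed = 1, pfp_threshold = 0.05,
                              max_exact = 2e5, min_pairs = 2) {
  common <- intersect(rownames(cord_matrix), rownames(followup_matrix))
  if (length(common) < 2L) stop("need at least 2 shared proteins")
  shared_subj <- intersect(colnames(cord_matrix), colnames(followup_matrix))
  if (is.null(pairs))
    pairs <- union(colnames(cord_matrix), colnames(followup_matrix))
  dropped <- setdiff(pairs, shared_subj)
  if (length(dropped)) {
    warning("unpaired subject(s) excluded: ", paste(dropped, collapse = ", "))
    pairs <- intersect(pairs, shared_subj)
  }
  if (!length(pairs)) stop("no paired subjects")
  d <- cord_matrix[common, pairs, drop = FALSE] -
    followup_matrix[common, pairs, drop = FALSE]
  n_obs <- rowSums(!is.na(d))
  usable <- n_obs >= max(1L, min(min_pairs, ncol(d)))
  if (!all(usable)) {
    warning(sum(!usable), " protein(s) observed in fewer than ", min_pairs,
            " pairs dropped")
    d <- d[usable, , drop = FALSE]
  }
  m <- nrow(d)
  k <- ncol(d)
  if (m < 2L) stop("need at least 2 usable proteins")
  complete <- !anyNA(d)

  pair_ranks <- function(sign) {
    vapply(seq_len(k), function(j)
      rank(sign * d[, j], ties.method = "average", na.last = "keep"),
      numeric(m))
  }
  ranks_up <- matrix(pair_ranks(-1), m)
  ranks_dn <- matrix(pair_ranks(1), m)
  k_i <- rowSums(!is.na(d))
  rp_up <- exp(rowSums(log(ranks_up), na.rm = TRUE) / k_i)
  rp_dn <- exp(rowSums(log(ranks_dn), na.rm = TRUE) / k_i)

  exact <- complete && m^k <= max_exact
  if (!exact && B < 1000)
    warning("B = ", B, " permutations is low; >= 1000 recommended")
  expected_at <- function(thresholds) {
    if (exact) return(rp_expected_exact(thresholds, m, k))
    set.seed(seed)
    if (complete) return(rp_expected_perm(thresholds, m, k, B))
    # permutation null preserving the missingness pattern: within each pair,
    # the observed ranks are shuffled among the observed proteins
    log_acc <- matrix(0, m, B)
    for (j in seq_len(k)) {
      obs <- which(!is.na(d[, j]))
      mj <- length(obs)
      if (!mj) next
      perm <- matrix(0, mj, B)
      for (b in seq_len(B)) perm[, b] <- sample.int(mj)
      log_acc[obs, ] <- log_acc[obs, ] + log(perm)
    }
    null_logrp <- sort(as.vector(log_acc / k_i))
    vapply(thresholds, function(t)
      findInterval(log(t) + 1e-9, null_logrp) / B, numeric(1))
  }
  pfp_of <- function(rp) {
    e <- expected_at(rp)
    r <- rank(rp, ties.method = "max")
    pfp <- e / r
    ord <- order(rp)
    pfp[ord] <- rev(cummin(rev(pfp[ord])))  # monotone in RP order
    pfp
  }
  pfp_up <- pfp_of(rp_up)
  pfp_dn <- pfp_of(rp_dn)

  out <- data.frame(protein_id = rownames(d),
                    rp_up = rp_up, pfp_up = pfp_up,
                    rp_down = rp_dn, pfp_down = pfp_dn,
                    direction = ifelse(rp_up <= rp_dn, "up", "down"),
                    significant = pmin(pfp_up, pfp_dn) < pfp_threshold,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "method") <- if (exact) "exact" else "permutation"
  attr(out, "B") <- if (exact) NA_integer_ else as.integer(B)
  attr(out, "seed") <- seed
  attr(out, "n_pairs") <- k
  out
}

#' Benjamini-Hochberg adjustment with missing values
#'
#' Standard step-up BH adjustment (via [stats::p.adjust()]); missing p-values
#' are excluded from the family and returned as missing.
#'
#' @param pvalues numeric vector of p-values in `[0, 1]`, `NA` allowed.
#' @return The BH-adjusted q-values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] < 0 | pvalues[ok] > 1))
    stop("p-values must lie in [0, 1]")
  q <- rep(NA_real_, length(pvalues))
  q[ok] <- p.adjust(pvalues[ok], method = "BH")
  q
}

#' Spearman correlation of cord-blood and follow-up levels across subjects
#'
#' For each protein and follow-up age bin, computes the Spearman rank
#' correlation across subjects between the subject's cord-blood value and its
#' follow-up value, with a two-sided p-value; all (protein, timepoint) tests
#' are pooled into one family for Benjamini-Hochberg adjustment, and tests
#' with adjusted q below `fdr` are flagged. Proteins or timepoints with fewer
#' than `min_subjects` complete subject pairs, or with a constant vector on
#' either side (rho undefined), are reported as missing.
#'
#' @param cord_matrix proteins x subjects matrix of cord-blood values.
#' @param followup an [expression_set()] of follow-up samples with annotation,
#'   or a list of proteins x subjects matrices named by timepoint.
#' @param bins,tol age-bin matching for the follow-up samples.
#' @param min_subjects minimum number of complete subject pairs (default 5).
#' @param fdr BH significance threshold (default 0.1).
#' @return A data frame with `protein_id`, `timepoint`, `n`, `rho`, `p`, `q`
#'   and `significant`.
#' @export
cord_followup_correlation <- function(cord_matrix, followup,
                                      bins = c(3, 6, 12, 18, 24, 36),
                                      tol = 1.5, min_subjects = 5, fdr = 0.1) {
  if (inherits(followup, "expression_set")) {
    ann <- followup$annotation
    if (is.null(ann)) stop("follow-up expression set has no annotation")
    bin <- assign_age_bins(ann, bins, tol)
    subj <- as.character(ann$subject_id)
    mats <- list()
    for (b in as.character(bins)) {
      cols <- which(!is.na(bin) & bin == b & !ann$is_cord)
      if (!length(cols)) next
      mat <- followup$values[, cols, drop = FALSE]
      colnames(mat) <- subj[cols]
      mat <- mat[, !duplicated(colnames(mat)), drop = FALSE]
      mats[[b]] <- mat
    }
  } else {
    mats <- followup
  }
  proteins <- intersect(rownames(cord_matrix),
                        unique(unlist(lapply(mats, rownames))))
  rows <- list()
  for (tp in names(mats)) {
    mat <- mats[[tp]]
    subjects <- intersect(colnames(cord_matrix), colnames(mat))
    for (p in intersect(proteins, rownames(mat))) {
      x <- cord_matrix[p, subjects]
      y <- mat[p, subjects]
      ok <- !is.na(x) & !is.na(y)
      n <- sum(ok)
      rho <- p_raw <- NA_real_
      if (n >= min_subjects && sd(x[ok]) > 0 && sd(y[ok]) > 0) {
        ct <- suppressWarnings(cor.test(x[ok], y[ok], method = "spearman",
                                        exact = FALSE))
        rho <- unname(ct$estimate)
        p_raw <- ct$p.value
      }
      rows[[length(rows) + 1L]] <- data.frame(
        protein_id = p, timepoint = tp, n = n, rho = rho, p = p_raw,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) stop("no testable (protein, timepoint) combinations")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$q <- bh_adjust(out$p)
  out$significant <- !is.na(out$q) & out$q < fdr
  out
}
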
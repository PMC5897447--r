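# Descriptive summaries: child-specific Z-scores, age-binned averages,
# paired fold changes and SRM reference normalisation.

#' Assign samples to nominal age bins
#'
#' Cord samples map to the `"cord"` bin; follow-up samples map to the nearest
#' nominal age within `tol` months, or `NA` when none is close enough.
#'
#' @param annotation sample annotation data frame.
#' @param bins nominal follow-up ages in months.
#' @param tol maximum distance to a nominal age, in months.
#' @return A character vector of bin labels (`"cord"`, `"3"`, ..., or `NA`).
#' @export
assign_age_bins <- function(annotation, bins = c(3, 6, 12, 18, 24, 36),
                            tol = 1.5) {
  vapply(seq_len(nrow(annotation)), function(i) {
    if (isTRUE(annotation$is_cord[i])) return("cord")
    d <- abs(annotation$age_months[i] - bins)
    j <- which.min(d)
    if (d[j] <= tol) as.character(bins[j]) else NA_character_
  }, character(1))
}

#' Child-specific Z-scores of protein trajectories
#'
#' For each protein and child, centres the child's trajectory on its own mean
#' and scales by its own (sample, n-1) standard deviation, ignoring missing
#' entries, so temporal shapes can be averaged across children regardless of
#' each child's absolute level. Trajectories with fewer than two non-missing
#' values or zero variance are set entirely missing and reported via a single
#' warning.
#'
#' @param es an [expression_set()] with annotation.
#' @return An [expression_set()] of Z-scores with the same dimensions;
#'   missing input entries stay missing.
#' @export
per_child_zscore <- function(es) {
  stopifnot(inherits(es, "expression_set"))
  if (is.null(es$annotation)) stop("expression set has no sample annotation")
  z <- es$values
  z[] <- NA_real_
  subj <- as.character(es$annotation$subject_id)
  n_degenerate <- 0L
  for (s in unique(subj)) {
    cols <- which(subj == s)
    sub <- es$values[, cols, drop = FALSE]
    m <- rowMeans(sub, na.rm = TRUE)
    sds <- apply(sub, 1L, sd, na.rm = TRUE)
    n_ok <- rowSums(!is.na(sub))
    usable <- n_ok >= 2L & !is.na(sds) & sds > 0
    n_degenerate <- n_degenerate + sum(!usable & n_ok >= 1L)
    zi <- (sub - m) / sds
    zi[!usable, ] <- NA_real_
    z[, cols] <- zi
  }
  if (n_degenerate > 0L)
    warning(n_degenerate,
            " (protein, child) trajectory(ies) with <2 values or zero ",
            "within-child sd set to missing")
  expression_set(z, es$annotation)
}

#' Average Z-scores by age group
#'
#' Averages child-specific Z-scores across children within nominal age bins,
#' yielding the proteins x age-groups matrix plotted as an age-trajectory
#' heatmap. A bin average uses the children with a value in that bin.
#'
#' @param z an [expression_set()] of Z-scores (see [per_child_zscore()]).
#' @param bins nominal follow-up ages in months.
#' @param tol bin assignment tolerance in months.
#' @param include_cord include a `"cord"` bin when cord samples are present.
#' @return A proteins x age-groups matrix of average Z-scores.
#' @export
average_zscores_by_age <- function(z, bins = c(3, 6, 12, 18, 24, 36),
                                   tol = 1.5, include_cord = TRUE) {
  stopifnot(inherits(z, "expression_set"))
  bin <- assign_age_bins(z$annotation, bins, tol)
  labels <- c(if (include_cord && any(bin == "cord", na.rm = TRUE)) "cord",
              as.character(bins))
  labels <- labels[labels %in% bin]
  out <- matrix(NA_real_, nrow(z$values), length(labels),
                dimnames = list(rownames(z$values), labels))
  for (b in labels) {
    cols <- which(!is.na(bin) & bin == b)
    out[, b] <- rowMeans(z$values[, cols, drop = FALSE], na.rm = TRUE)
  }
  out[is.nan(out)] <- NA_real_
  out
}

#' Median paired fold changes between co-processed subjects
#'
#' For pairs of subjects processed in the same batch, compares their log2
#' values at shared age bins. The fold change at a timepoint is computed on
#' the linear scale as \eqn{2^{|\Delta \log_2|}} (direction-agnostic
#' magnitude); the per-pair summary is the median across shared timepoints and
#' the per-protein summary the median across pairs.
#'
#' @param es an [expression_set()] with annotation.
#' @param subject_pairs list of length-2 character vectors of subject ids;
#'   when `NULL`, derived from batches containing exactly two subjects.
#' @param bins,tol age-bin matching (see [assign_age_bins()]).
#' @return A data frame with `protein_id`, one `pair_<a>_<b>` column of
#'   per-pair medians, and `median_fold_change` (median across pairs).
#' @export
paired_fold_changes <- function(es, subject_pairs = NULL,
                                bins = c(3, 6, 12, 18, 24, 36), tol = 1.5) {
  stopifnot(inherits(es, "expression_set"))
  ann <- es$annotation
  if (is.null(ann)) stop("expression set has no sample annotation")
  if (is.null(subject_pairs)) {
    by_batch <- tapply(as.character(ann$subject_id), ann$batch_id,
                       function(x) unique(x))
    subject_pairs <- Filter(function(p) length(p) == 2L, by_batch)
    if (!length(subject_pairs))
      stop("no batches with exactly two subjects; supply 'subject_pairs'")
  }
  bin <- assign_age_bins(ann, bins, tol)
  subj <- as.character(ann$subject_id)

  value_at <- function(s, b) {
    cols <- which(subj == s & !is.na(bin) & bin == b & !ann$is_cord)
    if (!length(cols)) return(rep(NA_real_, nrow(es$values)))
    es$values[, cols[1L]]
  }
  out <- data.frame(protein_id = rownames(es$values),
                    stringsAsFactors = FALSE)
  pair_cols <- character(0)
  for (p in subject_pairs) {
    a <- p[[1L]]; b <- p[[2L]]
    mats <- lapply(as.character(bins), function(bb)
      cbind(value_at(a, bb), value_at(b, bb)))
    shared_any <- FALSE
    fc <- matrix(NA_real_, nrow(es$values), length(bins))
    for (k in seq_along(mats)) {
      both <- !is.na(mats[[k]][, 1L]) & !is.na(mats[[k]][, 2L])
      if (any(both)) shared_any <- TRUE
      fc[both, k] <- 2^abs(mats[[k]][both, 1L] - mats[[k]][both, 2L])
    }
    if (!shared_any) {
      warning("pair (", a, ", ", b, ") has no shared timepoints; skipped")
      next
    }
    cn <- paste0("pair_", a, "_", b)
    out[[cn]] <- apply(fc, 1L, function(v)
      if (all(is.na(v))) NA_real_ else median(v, na.rm = TRUE))
    pair_cols <- c(pair_cols, cn)
  }
  if (!length(pair_cols)) stop("no usable subject pairs")
  out$median_fold_change <- apply(out[, pair_cols, drop = FALSE], 1L, function(v)
    if (all(is.na(v))) NA_real_ else median(unlist(v), na.rm = TRUE))
  out
}

#' Normalise a targeted SRM table against a reference protein
#'
#' Sums transition-level peak areas to protein-level intensities per sample,
#' divides by the endogenous reference protein's intensity in the same sample
#' (default A1BG, a protein with stable serum levels across early childhood),
#' and log2-transforms the ratios. The reference must be quantified with
#' nonzero intensity in every sample.
#'
#' @param srm data frame with columns `protein_id`, `peptide`, `transition`,
#'   `sample_id`, `intensity` (nonnegative peak areas).
#' @param reference_protein reference protein identifier (default `"A1BG"`).
#' @return A proteins x samples matrix of log2 reference-normalised
#'   intensities (`NA` where a protein was not measured in a sample).
#' @export
normalize_srm <- function(srm, reference_protein = "A1BG") {
  srm <- as.data.frame(srm)
  req <- c("protein_id", "peptide", "transition", "sample_id", "intensity")
  missing_cols <- setdiff(req, colnames(srm))
  if (length(missing_cols))
    stop("SRM table lacks column(s): ", paste(missing_cols, collapse = ", "))
  if (any(srm$intensity < 0)) stop("SRM intensities must be nonnegative")
  proteins <- unique(srm$protein_id)
  samples <- unique(srm$sample_id)
  totals <- matrix(NA_real_, length(proteins), length(samples),
                   dimnames = list(proteins, samples))
  agg <- tapply(srm$intensity, list(srm$protein_id, srm$sample_id), sum)
  totals[rownames(agg), colnames(agg)] <- agg
  if (!reference_protein %in% proteins)
    stop("reference protein '", reference_protein, "' not present")
  ref <- totals[reference_protein, ]
  bad <- names(ref)[is.na(ref) | ref <= 0]
  if (length(bad))
    stop("reference protein '", reference_protein,
         "' missing or zero in sample(s): ", paste(bad, collapse = ", "))
  norm <- sweep(totals, 2L, ref, "/")
  norm[!is.na(norm) & norm == 0] <- NA_real_  # unquantified, never -Inf
  log2(norm)
}
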
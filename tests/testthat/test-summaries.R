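# Z-score trajectories, age-binned averages, paired fold changes and SRM
# normalisation.

make_es <- function(values, subjects, ages, is_cord = FALSE, batches = NULL) {
  ann <- data.frame(sample_id = colnames(values), subject_id = subjects,
                    age_months = ages, gender = "girl", location = "Espoo",
                    is_cord = is_cord,
                    batch_id = if (is.null(batches)) "B1" else batches)
  expression_set(values, ann)
}

test_that("child-specific Z-scores standardise each trajectory", {
  v <- rbind(P1 = c(1, 2, 3, 5, 5, 5),
             P2 = c(2, 4, 6, 1, 2, 3))
  colnames(v) <- paste0("s", 1:6)
  es <- make_es(v, rep(c("A", "B"), each = 3), rep(c(3, 6, 12), 2))
  expect_warning(z <- per_child_zscore(es), "zero within-child sd")
  # trajectory (1,2,3) has sd 1 -> Z = (-1, 0, 1)
  expect_equal(unname(z$values["P1", 1:3]), c(-1, 0, 1))
  # constant trajectory (5,5,5) -> all missing
  expect_true(all(is.na(z$values["P1", 4:6])))
  # every usable trajectory has mean 0 and sd 1
  expect_equal(mean(z$values["P2", 1:3]), 0, tolerance = 1e-10)
  expect_equal(sd(z$values["P2", 4:6]), 1, tolerance = 1e-10)
})

test_that("Z-score averages pool children within age bins", {
  v <- rbind(P1 = c(-1, 0, 1, 1, 0, -1))
  colnames(v) <- paste0("s", 1:6)
  es <- make_es(v, rep(c("A", "B"), each = 3), c(3.2, 6.1, 11.8, 2.9, 6, 12))
  avg <- average_zscores_by_age(es, bins = c(3, 6, 12))
  # mirrored profiles cancel exactly
  expect_equal(unname(avg["P1", ]), c(0, 0, 0))
  # a sample too far from every bin is dropped
  es2 <- make_es(v, rep(c("A", "B"), each = 3), c(3, 6, 12, 3, 6, 20))
  avg2 <- average_zscores_by_age(es2, bins = c(3, 6, 12))
  expect_equal(unname(avg2["P1", "12"]), 1)
})

test_that("paired fold changes are direction-agnostic linear-scale medians", {
  # subject A at 2^3, subject B at 2^2 everywhere -> fold change 2 throughout
  v <- rbind(P1 = c(3, 3, 3, 2, 2, 2),
             P2 = c(5, 5, 5, 5, 5, 5))
  colnames(v) <- paste0("s", 1:6)
  es <- make_es(v, rep(c("A", "B"), each = 3), rep(c(3, 6, 12), 2))
  fc <- paired_fold_changes(es, subject_pairs = list(c("A", "B")),
                            bins = c(3, 6, 12))
  expect_equal(fc$median_fold_change[fc$protein_id == "P1"], 2)
  expect_equal(fc$median_fold_change[fc$protein_id == "P2"], 1)

  # per-timepoint fold changes {1.2, 1.6, 1.8} -> median 1.6
  v2 <- rbind(P1 = c(log2(1.2), log2(1.6), log2(1.8), 0, 0, 0))
  colnames(v2) <- paste0("s", 1:6)
  es2 <- make_es(v2, rep(c("A", "B"), each = 3), rep(c(3, 6, 12), 2))
  fc2 <- paired_fold_changes(es2, subject_pairs = list(c("A", "B")),
                             bins = c(3, 6, 12))
  expect_equal(fc2$median_fold_change, 1.6, tolerance = 1e-12)

  # pairs without shared timepoints are skipped with a warning
  v3 <- rbind(P1 = c(1, 1, NA, NA))
  colnames(v3) <- paste0("s", 1:4)
  es3 <- make_es(v3, c("A", "A", "B", "B"), c(3, 6, 12, 18))
  expect_warning(
    expect_error(paired_fold_changes(es3, subject_pairs = list(c("A", "B")),
                                     bins = c(3, 6, 12, 18)),
                 "no usable"),
    "no shared timepoints")
})

test_that("SRM normalisation sums transitions and divides by the reference", {
  srm <- data.frame(
    protein_id = rep(c("TGT", "A1BG"), each = 6),
    peptide = "pep", transition = rep(1:3, 4),
    sample_id = rep(rep(c("s1", "s2"), each = 3), 2),
    intensity = c(10, 20, 30, 15, 15, 0,   # TGT sums: 60, 30
                  20, 20, 20, 30, 30, 0))  # A1BG sums: 60, 60
  out <- normalize_srm(srm)
  expect_equal(out["TGT", "s1"], log2(1))
  expect_equal(out["TGT", "s2"], log2(0.5))
  expect_equal(out["A1BG", "s1"], 0)

  # reference zero in one sample -> error naming it
  srm2 <- srm
  srm2$intensity[srm2$protein_id == "A1BG" & srm2$sample_id == "s2"] <- 0
  expect_error(normalize_srm(srm2), "s2")
  expect_error(normalize_srm(transform(srm, intensity = -intensity)),
               "nonnegative")
})
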
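# Enumeration of the candidate models and covariate-effect selection.

test_that("exactly 16 pairwise distinct candidates are enumerated", {
  models <- enumerate_models()
  expect_length(models, 16L)
  labels <- vapply(models, `[[`, character(1), "label")
  expect_equal(anyDuplicated(labels), 0L)
  # every candidate carries the subject component and noise
  expect_true(all(vapply(models, function(m)
    all(c("id", "noise") %in% m$components), logical(1))))
  # the null model is the id + noise pair alone
  expect_equal(models[[1]]$components, c("id", "noise"))
  # age implies the age:id interaction, and only then
  expect_true(all(vapply(models, function(m)
    ("age:id" %in% m$components) == ("age" %in% m$covariates), logical(1))))
  # canonical order: sizes non-decreasing
  expect_true(!is.unsorted(lengths(lapply(models, `[[`, "covariates"))))
  # determinism
  expect_identical(models, enumerate_models())
})

test_that("selection flags a strong age effect and reports the thresholds", {
  ann <- simulate_design(study_design(n_subjects = 8), seed = 51)
  prot <- simulate_protein(ann, effect_config(age = 2, id = 0.3,
                                              noise = 0.5), seed = 51)
  sel <- select_effects(prot$value, ann, n_restarts = 3, seed = 1)
  expect_s3_class(sel, "agp_selection")
  expect_true(sel$flags[["age"]])
  expect_true(grepl("age", sel$best))
  expect_equal(nrow(sel$scores), 16L)
  expect_equal(sel$thresholds$delta, 0.05)

  # the best reported LOOCV score is never below the null model's
  null_score <- sel$scores$loocv_mlpd[sel$scores$model == "null"]
  expect_gte(max(sel$scores$loocv_mlpd), null_score - 1e-8)
})

test_that("adding covariates does not decrease the training likelihood", {
  ann <- simulate_design(study_design(n_subjects = 6), seed = 3)
  prot <- simulate_protein(ann, effect_config(age = 1, id = 0.5), seed = 7)
  sel <- select_effects(prot$value, ann, n_restarts = 3, seed = 2)
  sc <- sel$scores
  # compare each model against the nested one lacking its last covariate
  for (i in seq_len(nrow(sc))) {
    covs <- strsplit(sc$model[i], "+", fixed = TRUE)[[1]]
    if (identical(covs, "null")) next
    sub <- if (length(covs) > 1L) paste(covs[-length(covs)], collapse = "+")
      else "null"
    expect_gte(sc$log_marginal[i], sc$log_marginal[sc$model == sub] - 1e-2)
  }
  # CV scores, by contrast, are allowed to decrease (and typically do for
  # some of the overfitted candidates)
  expect_true(any(sc$loocv_mlpd < sc$loocv_mlpd[sc$model == "null"] + 1e-12))
})

test_that("proteins with too little data are skipped with a reason", {
  ann <- simulate_design(study_design(n_subjects = 4), seed = 5)
  y <- rep(NA_real_, nrow(ann))
  y[1:5] <- rnorm(5)
  sel <- select_effects(y, ann)
  expect_match(sel$skipped, "non-missing")
  y2 <- rep(NA_real_, nrow(ann))
  y2[ann$subject_id == "S01" & !ann$is_cord] <- rnorm(6) + 20
  sel2 <- select_effects(y2, ann, min_obs = 5)
  expect_match(sel2$skipped, "subject")
})

test_that("selection is invariant to protein and sample order", {
  ann <- simulate_design(study_design(n_subjects = 6), seed = 17)
  ds <- simulate_dataset(ann, n_proteins = 3,
                         class_mix = c(age = 0.4, id = 0.3, null = 0.3),
                         seed = 17)
  es <- ds$data
  tab <- select_proteome(es, seed = 9, n_restarts = 2)

  # permute protein rows
  perm <- c(3, 1, 2)
  es_rows <- expression_set(es$values[perm, ], es$annotation)
  tab_rows <- select_proteome(es_rows, seed = 9, n_restarts = 2)
  tab_rows <- tab_rows[match(tab$protein_id, tab_rows$protein_id), ]
  expect_equal(tab_rows$best_model, tab$best_model)
  expect_equal(tab_rows$flag_age, tab$flag_age)
  expect_equal(tab_rows$delta_age, tab$delta_age, tolerance = 1e-10)

  # permute sample columns
  sperm <- sample(ncol(es$values))
  es_cols <- expression_set(es$values[, sperm],
                            es$annotation[sperm, ])
  tab_cols <- select_proteome(es_cols, seed = 9, n_restarts = 2)
  expect_equal(tab_cols$best_model, tab$best_model)
  expect_equal(tab_cols$flag_age, tab$flag_age)
  expect_equal(tab_cols$delta_age, tab$delta_age, tolerance = 1e-6)
})

test_that("dominant subject offsets rank the id share above the age share", {
  ann <- simulate_design(study_design(n_subjects = 8), seed = 23)
  prot <- simulate_protein(ann, effect_config(age = 0.3, id = 3,
                                              noise = 0.5), seed = 23)
  sel <- select_effects(prot$value, ann, n_restarts = 3, seed = 4)
  expect_gt(sel$best_shares[["id"]], sel$shares[["age"]])
})
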
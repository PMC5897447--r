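# The synthetic-data generator: design, additive truth and dataset assembly.

test_that("the default design reproduces the cohort scale", {
  ann <- simulate_design(study_design(), seed = 1)
  fup <- ann[!ann$is_cord, ]
  expect_equal(nrow(fup), 15 * 6)       # 15 subjects x 6 nominal ages
  expect_equal(sum(ann$is_cord), 14)    # one child without a cord sample
  expect_equal(length(unique(ann$subject_id)), 15)
  expect_equal(as.integer(table(ann$location[!duplicated(ann$subject_id)])
                          [c("Espoo", "Tartu")]), c(11L, 4L))
  # batches hold at most two subjects
  expect_true(all(tapply(ann$subject_id, ann$batch_id,
                         function(x) length(unique(x))) <= 2))
  expect_true(all(ann$season_phase >= 0 & ann$season_phase < 12))
  expect_true(all(ann$age_months[ann$is_cord] == 0))

  # no jitter -> exactly nominal ages; same seed -> identical annotation
  ann0 <- simulate_design(study_design(age_jitter_sd = 0), seed = 2)
  expect_equal(ann0$age_months[!ann0$is_cord], ann0$nominal_age[!ann0$is_cord])
  expect_identical(simulate_design(study_design(), seed = 3),
                   simulate_design(study_design(), seed = 3))
})

test_that("simulated observations equal the stored component sum exactly", {
  ann <- simulate_design(study_design(n_subjects = 6), seed = 4)
  prot <- simulate_protein(ann, effect_config(age = 1, season = 0.5,
                                              gender = 0.3, location = 0.4,
                                              id = 0.6, age_id = 0.2),
                           seed = 11)
  expect_identical(prot$value, prot$baseline + rowSums(prot$components))
  # all-zero configuration gives identically zero components
  prot0 <- simulate_protein(ann, effect_config(noise = 0, cord_sd = 0,
                                               baseline_sd = 0,
                                               baseline_mean = 0), seed = 1)
  expect_true(all(prot0$value == 0))
  # determinism
  expect_identical(simulate_protein(ann, effect_config(age = 1), seed = 5),
                   simulate_protein(ann, effect_config(age = 1), seed = 5))
})

test_that("cord samples carry only subject, cord-offset and noise terms", {
  ann <- simulate_design(study_design(n_subjects = 6), seed = 7)
  prot <- simulate_protein(ann, effect_config(age = 1, season = 1,
                                              gender = 1, location = 1,
                                              id = 1), seed = 8)
  cord_rows <- ann$is_cord
  for (comp in c("age", "season", "gender", "location", "age_id"))
    expect_true(all(prot$components[cord_rows, comp] == 0))
  expect_true(all(prot$components[cord_rows, "cord"] != 0))
  expect_true(all(prot$components[!cord_rows, "cord"] == 0))
})

test_that("component variances are conserved in the aggregate", {
  ann <- simulate_design(study_design(n_subjects = 10, cord = FALSE,
                                      missing_prob = 0), seed = 10)
  # subject offsets: within-subject constant, between-subject variance ~ 1
  within <- replicate(150, {
    p <- simulate_protein(ann, effect_config(id = 1, noise = 0),
                          seed = sample.int(1e7, 1))
    c(w = max(tapply(p$components[, "id"], ann$subject_id, sd)),
      b = var(tapply(p$components[, "id"], ann$subject_id, mean)))
  })
  expect_equal(max(within["w", ]), 0)
  expect_equal(mean(within["b", ]), 1, tolerance = 0.15)

  # total sample variance ~ sum of configured variances (age term averaged
  # over the design, so its contribution is below its marginal variance)
  set.seed(99)
  eff <- effect_config(id = 0.5, noise = 1)
  v <- replicate(200, var(simulate_protein(ann, eff,
                                           seed = sample.int(1e7, 1))$value))
  expect_equal(mean(v), 1.5, tolerance = 0.1)
})

test_that("null observations look Gaussian over many replicates", {
  ann <- simulate_design(study_design(n_subjects = 5, cord = FALSE,
                                      missing_prob = 0), seed = 12)
  set.seed(12)
  obs <- as.vector(replicate(500, {
    p <- simulate_protein(ann, effect_config(), seed = sample.int(1e7, 1))
    p$value - p$baseline
  }))
  n <- length(obs)
  skew <- mean(obs^3)
  exkurt <- mean(obs^4) - 3
  # Monte-Carlo bounds: se(skew) ~ sqrt(6/n), se(kurt) ~ sqrt(24/n)
  expect_lt(abs(skew), 4 * sqrt(6 / n))
  expect_lt(abs(exkurt), 4 * sqrt(24 / n))
})

test_that("datasets honour the class mix, missingness and determinism", {
  ann <- simulate_design(study_design(n_subjects = 6), seed = 14)
  ds <- simulate_dataset(ann, n_proteins = 10,
                         class_mix = c(age = 0.5, null = 0.5),
                         missing_prob = 0, seed = 14, keep_truth = TRUE)
  expect_equal(sort(as.integer(table(ds$truth$class))), c(5L, 5L))
  expect_false(anyNA(ds$data$values))
  expect_equal(dim(ds$data$values), c(10L, nrow(ann)))
  # observation minus the stored component sum is the constant baseline
  pid <- ds$truth$protein_id[ds$truth$class == "age"][1]
  resid <- ds$data$values[pid, ] - rowSums(ds$components[[pid]])
  expect_equal(diff(range(resid)), 0)
  # the active class component is the one that moves
  expect_gt(sd(ds$components[[pid]][, "age"]), 0)
  expect_equal(sd(ds$components[[pid]][, "location"]), 0)

  ds2 <- simulate_dataset(ann, n_proteins = 10,
                          class_mix = c(age = 0.5, null = 0.5),
                          missing_prob = 0, seed = 14, keep_truth = TRUE)
  expect_identical(ds$data$values, ds2$data$values)
  expect_error(simulate_dataset(ann, 10, class_mix = c(age = 0.5)),
               "sum to 1")
  expect_error(simulate_dataset(ann, 10, class_mix = c(foo = 1)), "unknown")

  with_miss <- simulate_dataset(ann, n_proteins = 10,
                                class_mix = c(null = 1),
                                missing_prob = 0.2, seed = 3)
  expect_gt(mean(is.na(with_miss$data$values)), 0.1)
})

test_that("replicate-level tables reproduce the expression set after collapse", {
  ann <- simulate_design(study_design(n_subjects = 4, missing_prob = 0),
                         seed = 15)
  ds <- simulate_dataset(ann, n_proteins = 6, class_mix = c(null = 1),
                         missing_prob = 0.1, seed = 15)
  pg <- simulate_protein_groups(ds$data, rep_sd = 0, dropout = 0, seed = 1)
  es <- collapse_replicates(filter_identifications(pg$quant),
                            pg$replicate_map, ann)
  expect_equal(es$values[rownames(ds$data$values), colnames(ds$data$values)],
               ds$data$values, tolerance = 1e-9)
  # missingness round-trips as all-zero replicate triples
  expect_identical(is.na(es$values[rownames(ds$data$values), ]),
                   is.na(ds$data$values))
  # decoy rows exercise every identification filter
  filt <- filter_identifications(pg$quant)
  expect_false(any(c("REV_DECOY", "SITE_ONLY", "ONE_PEPTIDE", "RARELY_SEEN")
                   %in% filt$proteins$protein_id))
})
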
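# Shared fixtures, built in code.

# small follow-up-only annotation
toy_annotation <- function(n_subjects = 4, ages = c(3, 6, 12, 18, 24, 36),
                           seed = 1) {
  simulate_design(study_design(n_subjects = n_subjects, ages = ages,
                               cord = FALSE, missing_prob = 0),
                  seed = seed)
}

# a small fitted model reused across method tests
toy_fit <- function(seed = 1, formula = y ~ age + id, n_subjects = 5,
                    effects = effect_config(age = 1, id = 0.5)) {
  ann <- toy_annotation(n_subjects = n_subjects, seed = seed)
  prot <- simulate_protein(ann, effects, seed = seed + 100)
  df <- data.frame(y = prot$value, age = ann$age_months,
                   season = ann$season_phase, gender = ann$gender,
                   location = ann$location, id = ann$subject_id)
  agp(formula, df, n_restarts = 2, seed = seed)
}

# hand-built 6-protein x 12-run quantification table covering every
# identification-filter rule, including the 25%-of-runs boundary
toy_quant_table <- function() {
  runs <- sprintf("R%02d", 1:12)
  proteins <- data.frame(
    protein_id = c("KEEP_A", "KEEP_BOUNDARY", "REV", "SITE", "ONEPEP",
                   "RARE"),
    gene_name = c("A", "B", "R", "S", "O", "Q"),
    n_unique_peptides = c(5L, 3L, 6L, 4L, 1L, 3L),
    is_reverse = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE),
    is_mod_site_only = c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE),
    stringsAsFactors = FALSE)
  intens <- rbind(
    KEEP_A = rep(100, 12),           # quantified everywhere
    KEEP_BOUNDARY = c(rep(200, 3), rep(0, 9)),  # exactly 25% of runs
    REV = rep(150, 12),
    SITE = rep(150, 12),
    ONEPEP = rep(150, 12),
    RARE = c(rep(120, 2), rep(0, 10)))          # 2/12 = 16.7% of runs
  colnames(intens) <- runs
  protein_quant(proteins, intens)
}
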
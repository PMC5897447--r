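# Synthetic longitudinal proteomics data with additive ground truth.

#' Describe a longitudinal study design
#'
#' Encodes the sampling design of a birth-cohort proteomics study: subjects
#' split across two living environments, serum samples at nominal ages of
#' roughly 3, 6, 12, 18, 24 and 36 months (with jitter around the nominal
#' schedule), an optional umbilical-cord sample per subject, subjects
#' processed in batches of one or two, and a per-entry missingness
#' probability. The defaults mirror a 15-child cohort (11 subjects in one
#' location, 4 in the other, cord samples for all but one child).
#'
#' @param n_subjects number of children (default 15).
#' @param location_split named integer vector of subjects per location
#'   (default `c(Espoo = 11, Tartu = 4)`); must sum to `n_subjects`.
#' @param ages nominal follow-up ages in months.
#' @param age_jitter_sd standard deviation of the sampling-age jitter in
#'   months (default 0.3).
#' @param missing_prob per-entry probability that a collapsed value is
#'   missing (default 0.1).
#' @param cord generate cord samples.
#' @param n_no_cord number of subjects without a cord sample (default 1).
#' @param batch_size subjects per preparation batch (1 or 2; default 2).
#' @param seed default seed carried with the design.
#' @return An object of class `"study_design"`.
#' @export
study_design <- function(n_subjects = 15,
                         location_split = c(Espoo = 11, Tartu = 4),
                         ages = c(3, 6, 12, 18, 24, 36),
                         age_jitter_sd = 0.3, missing_prob = 0.1,
                         cord = TRUE, n_no_cord = 1, batch_size = 2,
                         seed = 1) {
  if (n_subjects != sum(location_split)) {
    # rescale the default split to the requested cohort size
    loc_names <- names(location_split)
    n1 <- max(1L, round(n_subjects * location_split[[1L]] /
                          sum(location_split)))
    n1 <- min(n1, n_subjects - 1L)
    if (n_subjects == 1L) n1 <- 1L
    location_split <- setNames(c(n1, n_subjects - n1), loc_names)
  }
  stopifnot(sum(location_split) == n_subjects,
            batch_size %in% c(1L, 2L), missing_prob >= 0, missing_prob < 1,
            age_jitter_sd >= 0)
  structure(list(n_subjects = n_subjects, location_split = location_split,
                 ages = ages, age_jitter_sd = age_jitter_sd,
                 missing_prob = missing_prob, cord = cord,
                 n_no_cord = n_no_cord, batch_size = batch_size, seed = seed),
            class = "study_design")
}

#' Simulate the sample annotation of a study design
#'
#' Draws a concrete sample annotation from a [study_design()]: jittered
#' sampling ages, balanced genders, the location split, batch assignments of
#' `batch_size` consecutive subjects, uniformly distributed birth months
#' implying a season phase (month-of-year in `[0, 12)`) for every sample, and
#' cord samples at age 0. Deterministic given the seed.
#'
#' @param design a [study_design()].
#' @param seed integer seed (defaults to the design's).
#' @return A sample annotation data frame with columns `sample_id`,
#'   `subject_id`, `age_months`, `nominal_age`, `gender`, `location`,
#'   `season_phase`, `batch_id`, `is_cord`.
#' @export
simulate_design <- function(design = study_design(), seed = design$seed) {
  stopifnot(inherits(design, "study_design"))
  set.seed(seed)
  n <- design$n_subjects
  subjects <- sprintf("S%02d", seq_len(n))
  genders <- sample(rep(c("girl", "boy"), length.out = n))
  locations <- rep(names(design$location_split), design$location_split)
  batches <- sprintf("B%02d", ceiling(seq_len(n) / design$batch_size))
  birth_month <- runif(n, 0, 12)

  rows <- list()
  for (i in seq_len(n)) {
    ages <- design$ages + rnorm(length(design$ages), 0, design$age_jitter_sd)
    ages <- pmax(ages, 0.5)
    rows[[i]] <- data.frame(
      sample_id = sprintf("%s_m%02d", subjects[i], design$ages),
      subject_id = subjects[i],
      age_months = ages,
      nominal_age = design$ages,
      gender = genders[i], location = locations[i],
      season_phase = (birth_month[i] + ages) %% 12,
      batch_id = batches[i], is_cord = FALSE,
      stringsAsFactors = FALSE)
  }
  ann <- do.call(rbind, rows)
  if (design$cord) {
    with_cord <- seq_len(max(0L, n - design$n_no_cord))
    cord <- data.frame(
      sample_id = sprintf("%s_cord", subjects[with_cord]),
      subject_id = subjects[with_cord],
      age_months = 0, nominal_age = 0,
      gender = genders[with_cord], location = locations[with_cord],
      season_phase = birth_month[with_cord] %% 12,
      batch_id = batches[with_cord], is_cord = TRUE,
      stringsAsFactors = FALSE)
    ann <- rbind(ann, cord)
  }
  rownames(ann) <- NULL
  ann
}

#' Configure the additive effects of a synthetic protein
#'
#' Per-component signal variances of the generating additive model (log2
#' intensity scale), the lengthscales of the smooth components, the noise
#' variance, the cord-specific offset, and the per-protein baseline level.
#' A variance of 0 switches a component off. The default is a null protein:
#' noise only (variance 1) around a baseline drawn from N(25, 2^2), the
#' typical magnitude of log2 LFQ intensities.
#'
#' @param age,season,gender,location,id,age_id signal variances of the
#'   respective components (default 0).
#' @param noise observation noise variance (default 1).
#' @param age_lengthscale SE lengthscale of the age component in months
#'   (default 6, concentrating the drawn trajectories' change in the first
#'   year of life as observed for real age-associated serum proteins).
#' @param season_lengthscale periodic lengthscale of the seasonal component
#'   (default 1).
#' @param cord_sd sd of the per-protein cord-specific offset (default 1).
#' @param baseline_mean,baseline_sd distribution of the per-protein baseline
#'   log2 intensity.
#' @return An object of class `"effect_config"`.
#' @export
effect_config <- function(age = 0, season = 0, gender = 0, location = 0,
                          id = 0, age_id = 0, noise = 1,
                          age_lengthscale = 6, season_lengthscale = 1,
                          cord_sd = 1, baseline_mean = 25, baseline_sd = 2) {
  vars <- c(age = age, season = season, gender = gender, location = location,
            id = id, age_id = age_id, noise = noise)
  if (any(vars < 0)) stop("variances must be nonnegative")
  if (age_lengthscale <= 0 || season_lengthscale <= 0)
    stop("lengthscales must be positive")
  structure(list(age = age, season = season, gender = gender,
                 location = location, id = id, age_id = age_id, noise = noise,
                 age_lengthscale = age_lengthscale,
                 season_lengthscale = season_lengthscale, cord_sd = cord_sd,
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd),
            class = "effect_config")
}

# draw from N(0, K) with a tiny diagonal stabiliser
draw_gp <- function(K) {
  n <- nrow(K)
  diag(K) <- diag(K) + 1e-10
  drop(crossprod(chol(K), rnorm(n)))
}

#' Simulate one protein trajectory with additive ground truth
#'
#' Draws each active component from its prior — a smooth squared-exponential
#' function of age, a periodic function of season phase, level offsets for
#' gender and location, per-subject offsets for individual variation,
#' per-subject smooth age deviations for the age-by-individual interaction —
#' and adds Gaussian noise. Cord samples receive the subject offset, a
#' protein-level cord-specific offset and noise, but no age/season/gender/
#' location components (cord serum is treated as its own regime rather than an
#' age-0 extrapolation). The observation equals the stored component sum
#' exactly, by construction.
#'
#' @param annotation sample annotation (see [simulate_design()]).
#' @param effects an [effect_config()].
#' @param seed integer seed.
#' @return An object of class `"synthetic_protein"`: list with `value` (log2
#'   intensities per annotation row), `components` (matrix of the additive
#'   truth, one column per component including noise and cord), and
#'   `baseline`.
#' @export
simulate_protein <- function(annotation, effects = effect_config(), seed = 1) {
  stopifnot(inherits(effects, "effect_config"))
  set.seed(seed)
  n <- nrow(annotation)
  follow <- !annotation$is_cord
  comp_names <- c("age", "season", "gender", "location", "id", "age_id",
                  "cord", "noise")
  comps <- matrix(0, n, length(comp_names),
                  dimnames = list(annotation$sample_id, comp_names))

  baseline <- rnorm(1, effects$baseline_mean, effects$baseline_sd)

  if (effects$age > 0 && any(follow)) {
    x <- annotation$age_months[follow]
    K <- effects$age * exp(-outer(x, x, "-")^2 /
                             (2 * effects$age_lengthscale^2))
    comps[follow, "age"] <- draw_gp(K)
  }
  if (effects$season > 0 && any(follow)) {
    x <- annotation$season_phase[follow]
    K <- effects$season * exp(-2 * sin(pi * outer(x, x, "-") / 12)^2 /
                                effects$season_lengthscale^2)
    comps[follow, "season"] <- draw_gp(K)
  }
  if (effects$gender > 0) {
    levs <- unique(as.character(annotation$gender))
    offs <- setNames(rnorm(length(levs), 0, sqrt(effects$gender)), levs)
    comps[follow, "gender"] <- offs[as.character(annotation$gender[follow])]
  }
  if (effects$location > 0) {
    levs <- unique(as.character(annotation$location))
    offs <- setNames(rnorm(length(levs), 0, sqrt(effects$location)), levs)
    comps[follow, "location"] <-
      offs[as.character(annotation$location[follow])]
  }
  subj <- as.character(annotation$subject_id)
  if (effects$id > 0) {
    levs <- unique(subj)
    offs <- setNames(rnorm(length(levs), 0, sqrt(effects$id)), levs)
    comps[, "id"] <- offs[subj]  # persists into the cord sample
  }
  if (effects$age_id > 0) {
    for (s in unique(subj)) {
      idx <- which(subj == s & follow)
      if (!length(idx)) next
      x <- annotation$age_months[idx]
      K <- effects$age_id * exp(-outer(x, x, "-")^2 /
                                  (2 * effects$age_lengthscale^2))
      comps[idx, "age_id"] <- draw_gp(K)
    }
  }
  if (any(!follow) && effects$cord_sd > 0) {
    comps[!follow, "cord"] <- rnorm(1, 0, effects$cord_sd)
  }
  comps[, "noise"] <- rnorm(n, 0, sqrt(effects$noise))

  structure(list(value = baseline + rowSums(comps), components = comps,
                 baseline = baseline, effects = effects, seed = seed),
            class = "synthetic_protein")
}

#' Simulate a full synthetic expression dataset with truth labels
#'
#' Generates `n_proteins` proteins whose effect classes are assigned according
#' to `class_mix` (a named vector of fractions over `"age"`, `"season"`,
#' `"gender"`, `"location"`, `"id"`, `"null"`), activates the corresponding
#' component of each protein at variance `effect_var`, applies per-entry
#' missingness, and returns the expression matrix together with the
#' ground-truth labels, for power and type-I-error studies of the selection
#' pipeline.
#'
#' @param annotation sample annotation (see [simulate_design()]).
#' @param n_proteins number of proteins.
#' @param class_mix named fractions summing to 1 (default 40% age, 10%
#'   location, 20% id, 30% null).
#' @param effects base [effect_config()] shared by all proteins; the active
#'   class component is set to `effect_var`.
#' @param effect_var signal variance of the active component (default 1,
#'   i.e. effect sd equal to the default noise sd).
#' @param missing_prob per-entry missingness probability (default 0.1).
#' @param seed integer seed.
#' @param keep_truth keep per-protein component matrices.
#' @return A list with `data` (an [expression_set()]), `truth` (data frame
#'   `protein_id`, `class`, `seed`) and, if `keep_truth`, `components`.
#' @export
simulate_dataset <- function(annotation, n_proteins = 24,
                             class_mix = c(age = 0.4, location = 0.1,
                                           id = 0.2, null = 0.3),
                             effects = effect_config(), effect_var = 1,
                             missing_prob = 0.1, seed = 1,
                             keep_truth = FALSE) {
  if (abs(sum(class_mix) - 1) > 1e-8)
    stop("class fractions must sum to 1")
  known <- c("age", "season", "gender", "location", "id", "age_id", "null")
  bad <- setdiff(names(class_mix), known)
  if (length(bad)) stop("unknown effect class(es): ",
                        paste(bad, collapse = ", "))
  # largest-remainder apportioning of classes
  raw <- class_mix * n_proteins
  counts <- floor(raw)
  rem <- n_proteins - sum(counts)
  if (rem > 0) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1
  }
  classes <- rep(names(counts), counts)

  set.seed(seed)
  classes <- sample(classes)
  protein_seeds <- sample.int(.Machine$integer.max - 1L, n_proteins)
  ids <- sprintf("P%03d", seq_len(n_proteins))

  values <- matrix(NA_real_, n_proteins, nrow(annotation),
                   dimnames = list(ids, annotation$sample_id))
  components <- if (keep_truth) vector("list", n_proteins) else NULL
  for (i in seq_len(n_proteins)) {
    eff <- effects
    if (classes[i] != "null") eff[[classes[i]]] <- effect_var
    class(eff) <- "effect_config"
    prot <- simulate_protein(annotation, eff, seed = protein_seeds[i])
    values[i, ] <- prot$value
    if (keep_truth) components[[i]] <- prot$components
  }
  if (missing_prob > 0) {
    mask <- matrix(runif(length(values)) < missing_prob, nrow(values))
    values[mask] <- NA_real_
  }
  truth <- data.frame(protein_id = ids, class = classes,
                      seed = protein_seeds, stringsAsFactors = FALSE)
  out <- list(data = expression_set(values, annotation), truth = truth)
  if (keep_truth) {
    names(components) <- ids
    out$components <- components
  }
  out
}

#' Expand an expression set into a replicate-level protein-group table
#'
#' Emulates the raw quantification export upstream of replicate collapsing:
#' each sample becomes `n_replicates` LC-MS/MS runs whose linear-scale
#' intensities scatter log-normally around `2^value`; missing sample values
#' yield all-zero runs and individual runs drop out at rate `dropout`.
#' Optionally appends decoy-style rows exercising every identification
#' filter: a reverse hit, a modification-site-only hit, a single-peptide
#' protein and a protein quantified in too few runs.
#'
#' @param es an [expression_set()].
#' @param n_replicates technical replicates per sample (default 3).
#' @param rep_sd replicate scatter on the log2 scale (default 0.15, about a
#'   10% coefficient of variation).
#' @param dropout per-run probability of a missed quantification (default
#'   0.02).
#' @param decoys append the filter-exercising rows.
#' @param seed integer seed.
#' @return A list with `quant` (a [protein_quant()]) and `replicate_map`.
#' @export
simulate_protein_groups <- function(es, n_replicates = 3, rep_sd = 0.15,
                                    dropout = 0.02, decoys = TRUE, seed = 1) {
  stopifnot(inherits(es, "expression_set"))
  set.seed(seed)
  samples <- colnames(es$values)
  runs <- as.vector(t(outer(samples, seq_len(n_replicates),
                            function(s, r) sprintf("%s_r%d", s, r))))
  replicate_map <- data.frame(run_id = runs,
                              sample_id = rep(samples, each = n_replicates),
                              stringsAsFactors = FALSE)
  nprot <- nrow(es$values)
  intens <- matrix(0, nprot, length(runs),
                   dimnames = list(rownames(es$values), runs))
  for (j in seq_along(runs)) {
    s <- replicate_map$sample_id[j]
    v <- es$values[, s]
    x <- 2^(v + rnorm(nprot, 0, rep_sd))
    x[is.na(v)] <- 0
    x[runif(nprot) < dropout] <- 0
    intens[, j] <- x
  }
  proteins <- data.frame(protein_id = rownames(es$values),
                         gene_name = rownames(es$values),
                         n_unique_peptides = 2L + rpois(nprot, 4),
                         is_reverse = FALSE, is_mod_site_only = FALSE,
                         stringsAsFactors = FALSE)
  if (decoys) {
    level <- 2^mean(es$values, na.rm = TRUE)
    few <- pmax(2L, floor(length(runs) * 0.25) - 1L)
    deco_int <- rbind(
      REV_DECOY = level * runif(length(runs), 0.5, 2),
      SITE_ONLY = level * runif(length(runs), 0.5, 2),
      ONE_PEPTIDE = level * runif(length(runs), 0.5, 2),
      RARELY_SEEN = c(level * runif(few, 0.5, 2),
                      rep(0, length(runs) - few)))
    deco <- data.frame(
      protein_id = rownames(deco_int), gene_name = rownames(deco_int),
      n_unique_peptides = c(5L, 4L, 1L, 5L),
      is_reverse = c(TRUE, FALSE, FALSE, FALSE),
      is_mod_site_only = c(FALSE, TRUE, FALSE, FALSE),
      stringsAsFactors = FALSE)
    proteins <- rbind(proteins, deco)
    intens <- rbind(intens, deco_int)
  }
  list(quant = protein_quant(proteins, intens), replicate_map = replicate_map)
}

#' Write a protein-group table in the MaxQuant dialect
#'
#' @param x a [protein_quant()].
#' @param path output TSV path.
#' @param intensity_prefix intensity column prefix.
#' @return Invisibly, `path`.
#' @export
write_protein_groups <- function(x, path,
                                 intensity_prefix = "LFQ intensity ") {
  stopifnot(inherits(x, "protein_quant"))
  df <- data.frame(
    "Protein IDs" = x$proteins$protein_id,
    "Gene names" = x$proteins$gene_name,
    "Unique peptides" = x$proteins$n_unique_peptides,
    "Reverse" = ifelse(x$proteins$is_reverse, "+", ""),
    "Only identified by site" = ifelse(x$proteins$is_mod_site_only, "+", ""),
    check.names = FALSE, stringsAsFactors = FALSE)
  intens <- as.data.frame(x$intensities)
  colnames(intens) <- paste0(intensity_prefix, colnames(x$intensities))
  write.table(cbind(df, intens), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
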
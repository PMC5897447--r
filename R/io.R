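# Reading, filtering and collapsing label-free protein quantification tables.

#' Protein quantification table
#'
#' Container for a parsed protein-group table: identification metadata plus a
#' proteins x runs matrix of raw (linear-scale) intensities in which 0 encodes
#' "not quantified".
#'
#' @param proteins data frame with columns `protein_id`, `gene_name`,
#'   `n_unique_peptides`, `is_reverse`, `is_mod_site_only`.
#' @param intensities numeric matrix (proteins x runs) with unique run
#'   identifiers as column names; values finite and nonnegative.
#' @return An object of class `"protein_quant"`.
#' @export
protein_quant <- function(proteins, intensities) {
  stopifnot(is.data.frame(proteins), is.matrix(intensities))
  req <- c("protein_id", "gene_name", "n_unique_peptides", "is_reverse",
           "is_mod_site_only")
  missing_cols <- setdiff(req, colnames(proteins))
  if (length(missing_cols))
    stop("protein table lacks column(s): ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(proteins$protein_id))
    stop("duplicate protein_id values: ",
         paste(unique(proteins$protein_id[duplicated(proteins$protein_id)]),
               collapse = ", "))
  if (anyDuplicated(colnames(intensities)))
    stop("run identifiers must be unique")
  if (!all(is.finite(intensities)))
    stop("intensities must be finite")
  if (any(intensities < 0))
    stop("intensities must be nonnegative (0 encodes 'not quantified')")
  if (!is.logical(proteins$is_reverse) || !is.logical(proteins$is_mod_site_only))
    stop("identification flags must be logical")
  if (any(proteins$n_unique_peptides < 0))
    stop("unique-peptide counts must be nonnegative")
  if (nrow(proteins) != nrow(intensities))
    stop("metadata and intensity matrix disagree on the number of proteins")
  rownames(intensities) <- proteins$protein_id
  structure(list(proteins = proteins, intensities = intensities),
            class = "protein_quant")
}

#' @export
print.protein_quant <- function(x, ...) {
  cat("protein quantification table: ", nrow(x$proteins), " protein group(s) x ",
      ncol(x$intensities), " run(s)\n", sep = "")
  cat("  reverse hits: ", sum(x$proteins$is_reverse),
      "; modification-site-only: ", sum(x$proteins$is_mod_site_only), "\n",
      sep = "")
  invisible(x)
}

#' @export
dim.protein_quant <- function(x) dim(x$intensities)

parse_flag <- function(x) {
  if (is.logical(x)) return(ifelse(is.na(x), FALSE, x))
  x <- trimws(as.character(x))
  !is.na(x) & x %in% c("+", "TRUE", "True", "true", "1", "yes")
}

#' Read a protein-group quantification table
#'
#' Parses a tab-delimited protein-group table in the MaxQuant `proteinGroups`
#' dialect: one row per protein group, identification metadata columns, and
#' one intensity column per LC-MS/MS run named `<intensity_prefix><run id>`.
#' Empty intensity cells are parsed as 0 ("not quantified"); cells that fail
#' numeric parsing are reported with a warning and also set to 0.
#'
#' @param path path to the tab-delimited file.
#' @param run_ids optional run identifiers; when `NULL` all columns starting
#'   with `intensity_prefix` are used.
#' @param intensity_prefix prefix of the intensity columns (default
#'   `"LFQ intensity "`).
#' @param id_col,gene_col,peptide_col,reverse_col,site_col column-name dialect
#'   of the metadata columns.
#' @return A [protein_quant()] object.
#' @export
read_protein_groups <- function(path, run_ids = NULL,
                                intensity_prefix = "LFQ intensity ",
                                id_col = "Protein IDs",
                                gene_col = "Gene names",
                                peptide_col = "Unique peptides",
                                reverse_col = "Reverse",
                                site_col = "Only identified by site") {
  df <- read.delim(path, sep = "\t", check.names = FALSE, quote = "",
                   stringsAsFactors = FALSE)
  for (cn in c(id_col, peptide_col, reverse_col, site_col)) {
    if (!cn %in% colnames(df))
      stop("required column '", cn, "' not found in ", path)
  }
  if (is.null(run_ids)) {
    int_cols <- grep(paste0("^", intensity_prefix), colnames(df), value = TRUE)
    if (!length(int_cols))
      stop("no intensity columns with prefix '", intensity_prefix,
           "' found in ", path)
    run_ids <- substring(int_cols, nchar(intensity_prefix) + 1L)
  } else {
    int_cols <- paste0(intensity_prefix, run_ids)
    absent <- setdiff(int_cols, colnames(df))
    if (length(absent))
      stop("required column '", absent[1L], "' not found in ", path)
  }
  raw <- df[int_cols]
  n_bad <- 0L
  intens <- vapply(raw, function(x) {
    ch <- trimws(as.character(x))
    num <- suppressWarnings(as.numeric(ch))
    bad <- is.na(num) & !(is.na(ch) | ch %in% c("", "NA", "NaN"))
    n_bad <<- n_bad + sum(bad)
    num[is.na(num)] <- 0
    num
  }, numeric(nrow(df)))
  intens <- matrix(intens, nrow = nrow(df),
                   dimnames = list(NULL, run_ids))
  if (n_bad > 0L)
    warning(n_bad, " malformed numeric intensity cell(s) set to 0")
  peps <- suppressWarnings(as.integer(df[[peptide_col]]))
  if (anyNA(peps))
    stop("non-integer values in column '", peptide_col, "'")
  proteins <- data.frame(
    protein_id = as.character(df[[id_col]]),
    gene_name = if (gene_col %in% colnames(df))
      as.character(df[[gene_col]]) else NA_character_,
    n_unique_peptides = peps,
    is_reverse = parse_flag(df[[reverse_col]]),
    is_mod_site_only = parse_flag(df[[site_col]]),
    stringsAsFactors = FALSE)
  protein_quant(proteins, intens)
}

#' Filter protein identifications
#'
#' Removes reverse (decoy) hits, proteins identified only by modification
#' site, proteins identified with fewer than `min_unique_peptides` unique
#' peptides, and proteins quantified (nonzero intensity) in strictly less than
#' `min_run_fraction` of the runs. The boundary is kept: a protein quantified
#' in exactly 25% of the runs survives the default filter. Row order is
#' preserved and the operation is idempotent.
#'
#' @param x a [protein_quant()] table.
#' @param min_unique_peptides minimum unique-peptide count (default 2).
#' @param min_run_fraction minimum fraction of runs with nonzero intensity,
#'   in (0, 1] (default 0.25).
#' @return The filtered [protein_quant()] table.
#' @export
filter_identifications <- function(x, min_unique_peptides = 2,
                                   min_run_fraction = 0.25) {
  stopifnot(inherits(x, "protein_quant"))
  if (min_run_fraction <= 0 || min_run_fraction > 1)
    stop("'min_run_fraction' must be in (0, 1]")
  if (min_unique_peptides < 1)
    stop("'min_unique_peptides' must be >= 1")
  frac <- rowMeans(x$intensities > 0)
  keep <- !x$proteins$is_reverse & !x$proteins$is_mod_site_only &
    x$proteins$n_unique_peptides >= min_unique_peptides &
    frac >= min_run_fraction
  if (!any(keep)) warning("no proteins pass the identification filter")
  protein_quant(x$proteins[keep, , drop = FALSE],
                x$intensities[keep, , drop = FALSE])
}

#' Expression matrix with sample annotation
#'
#' A proteins x samples matrix of log2 intensities with explicit missing
#' entries (`NA`), optionally linked to a sample annotation table. Missing
#' values are never imputed by any operation in this package.
#'
#' @param values numeric matrix with protein identifiers as row names and
#'   sample identifiers as column names.
#' @param annotation optional sample annotation data frame containing at least
#'   `sample_id`, `subject_id`, `age_months`, `gender`, `location`; reordered
#'   to match the matrix columns.
#' @return An object of class `"expression_set"`.
#' @export
expression_set <- function(values, annotation = NULL) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' needs protein row names and sample column names")
  if (!is.null(annotation)) {
    annotation <- validate_annotation(annotation)
    absent <- setdiff(colnames(values), annotation$sample_id)
    if (length(absent))
      stop("annotation lacks sample(s): ", paste(absent, collapse = ", "))
    annotation <- annotation[match(colnames(values), annotation$sample_id), ,
                             drop = FALSE]
    rownames(annotation) <- NULL
  }
  structure(list(values = values, annotation = annotation),
            class = "expression_set")
}

#' @export
print.expression_set <- function(x, ...) {
  cat("expression set: ", nrow(x$values), " protein(s) x ", ncol(x$values),
      " sample(s); ", round(100 * mean(is.na(x$values)), 1),
      "% missing\n", sep = "")
  if (!is.null(x$annotation))
    cat("  ", length(unique(x$annotation$subject_id)), " subject(s); ",
        sum(x$annotation$is_cord), " cord sample(s)\n", sep = "")
  invisible(x)
}

#' @export
dim.expression_set <- function(x) dim(x$values)

#' @export
`[.expression_set` <- function(x, i, j, ...) {
  v <- x$values[i, j, drop = FALSE]
  ann <- x$annotation
  if (!is.null(ann)) ann <- ann[match(colnames(v), ann$sample_id), ,
                                drop = FALSE]
  expression_set(v, ann)
}

#' Collapse technical replicates to sample-level log2 intensities
#'
#' Per protein and biological sample, takes the median of the nonzero
#' replicate-run intensities; a protein with all-zero replicates in a sample
#' becomes missing (`NA`). The collapsed values are then log2-transformed.
#' The median is invariant to the order of the replicate runs.
#'
#' @param x a [protein_quant()] table.
#' @param replicate_map data frame with columns `run_id` and `sample_id`
#'   assigning every run to its biological sample; a run without an assignment
#'   is an error.
#' @param annotation optional sample annotation attached to the result.
#' @return An [expression_set()] of log2 intensities.
#' @export
collapse_replicates <- function(x, replicate_map, annotation = NULL) {
  stopifnot(inherits(x, "protein_quant"))
  replicate_map <- as.data.frame(replicate_map)
  if (!all(c("run_id", "sample_id") %in% colnames(replicate_map)))
    stop("'replicate_map' needs columns run_id and sample_id")
  runs <- colnames(x$intensities)
  unassigned <- setdiff(runs, replicate_map$run_id)
  if (length(unassigned))
    stop("run(s) without sample assignment: ",
         paste(unassigned, collapse = ", "))
  samples <- unique(replicate_map$sample_id[replicate_map$run_id %in% runs])
  vals <- matrix(NA_real_, nrow(x$intensities), length(samples),
                 dimnames = list(rownames(x$intensities), samples))
  for (s in samples) {
    rs <- replicate_map$run_id[replicate_map$sample_id == s]
    rs <- intersect(rs, runs)
    sub <- x$intensities[, rs, drop = FALSE]
    vals[, s] <- apply(sub, 1L, function(v) {
      nz <- v[v > 0]
      if (!length(nz)) NA_real_ else median(nz)
    })
  }
  expression_set(log2(vals), annotation)
}

#' Filter proteins by sample coverage
#'
#' Keeps proteins with a non-missing value in at least `min_sample_fraction`
#' of the samples (the rule removes strictly below the threshold: presence in
#' exactly 50% of the samples survives the default filter).
#'
#' @param es an [expression_set()].
#' @param min_sample_fraction minimum fraction of samples quantified, in
#'   `[0, 1]` (default 0.5). 0 keeps everything.
#' @return The filtered [expression_set()].
#' @export
filter_sample_coverage <- function(es, min_sample_fraction = 0.5) {
  stopifnot(inherits(es, "expression_set"))
  if (min_sample_fraction < 0 || min_sample_fraction > 1)
    stop("'min_sample_fraction' must be in [0, 1]")
  keep <- rowMeans(!is.na(es$values)) >= min_sample_fraction
  expression_set(es$values[keep, , drop = FALSE], es$annotation)
}

validate_annotation <- function(annotation) {
  annotation <- as.data.frame(annotation)
  req <- c("sample_id", "subject_id", "age_months", "gender", "location")
  missing_cols <- setdiff(req, colnames(annotation))
  if (length(missing_cols))
    stop("sample annotation lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  if (!"is_cord" %in% colnames(annotation)) annotation$is_cord <- FALSE
  annotation$is_cord <- as.logical(annotation$is_cord)
  if (!"season_phase" %in% colnames(annotation))
    annotation$season_phase <- NA_real_
  if (!"batch_id" %in% colnames(annotation))
    annotation$batch_id <- NA_character_
  if (anyDuplicated(annotation$sample_id))
    stop("duplicate sample_id values in annotation")
  for (cn in c("gender", "location")) {
    per_subj <- tapply(as.character(annotation[[cn]]), annotation$subject_id,
                       function(x) length(unique(x)))
    if (any(per_subj > 1L))
      stop("subject(s) mapped to more than one ", cn, " level")
  }
  if (any(annotation$age_months[annotation$is_cord] != 0))
    stop("cord samples must have age 0")
  if (any(annotation$age_months[!annotation$is_cord] <= 0))
    stop("non-cord samples must have age > 0")
  ok_phase <- is.na(annotation$season_phase) |
    (annotation$season_phase >= 0 & annotation$season_phase < 12)
  if (!all(ok_phase))
    stop("season_phase must lie in [0, 12)")
  annotation
}

#' Read a sample annotation table
#'
#' Accepts tab-separated (`.tsv`/`.txt`) or comma-separated (`.csv`) files
#' with columns `sample_id`, `subject_id`, `age_months`, `gender`, `location`
#' and optionally `season_phase` (month-of-year in `[0, 12)`), `batch_id`,
#' `is_cord` and `nominal_age`. Invariants (one gender/location per subject,
#' cord samples at age 0) are checked.
#'
#' @param path path to the annotation file.
#' @return A validated annotation data frame.
#' @export
read_sample_annotation <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  validate_annotation(read.delim(path, sep = sep, stringsAsFactors = FALSE))
}

#' Read a replicate-to-sample map
#'
#' @param path tab-separated file with columns `run_id` and `sample_id`.
#' @return A data frame.
#' @export
read_replicate_map <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("run_id", "sample_id") %in% colnames(df)))
    stop("replicate map needs columns run_id and sample_id")
  df
}

#' Write an expression matrix as TSV
#'
#' Writes the proteins x samples matrix with a leading `protein_id` column and
#' `NA` for missing values.
#'
#' @param es an [expression_set()] or a plain matrix.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_expression_matrix <- function(es, path) {
  values <- if (inherits(es, "expression_set")) es$values else es
  df <- data.frame(protein_id = rownames(values), values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an expression matrix written by [write_expression_matrix()]
#'
#' @param path TSV path.
#' @param annotation optional annotation to attach.
#' @return An [expression_set()].
#' @export
read_expression_matrix <- function(path, annotation = NULL) {
  df <- read.delim(path, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  values <- as.matrix(df[, -1L, drop = FALSE])
  rownames(values) <- df[[1L]]
  expression_set(values, annotation)
}
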
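#' Construct a feature matrix
#'
#' The central tabular object of the pipeline: a subjects x metabolites
#' intensity matrix plus identifiers and a processing-stage tag. Missing
#' entries (below the instrument's limit of detection) are `NA` and are only
#' legal at the `"raw"` stage; the `"imputed"` and `"log_normalized"` stages
#' are complete matrices.
#'
#' Feature *ids* must be unique; display *names* may repeat (GC-MS libraries
#' can match the same compound name to several chromatographic features), so
#' all joins in the package go through ids.
#'
#' @param values numeric matrix, subjects in rows, features in columns.
#' @param feature_ids unique feature identifiers (default: column names).
#' @param subject_ids unique subject identifiers (default: row names).
#' @param feature_names display names, duplicates allowed (default: ids).
#' @param stage one of `"raw"`, `"imputed"`, `"log_normalized"`.
#' @return an object of class `feature_matrix`.
#' @export
feature_matrix <- function(values,
                           feature_ids = colnames(values),
                           subject_ids = rownames(values),
                           feature_names = feature_ids,
                           stage = c("raw", "imputed", "log_normalized")) {
  stage <- match.arg(stage)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(feature_ids))
    feature_ids <- sprintf("M%03d", seq_len(ncol(values)))
  if (is.null(subject_ids))
    subject_ids <- sprintf("S%03d", seq_len(nrow(values)))
  feature_ids <- as.character(feature_ids)
  subject_ids <- as.character(subject_ids)
  feature_names <- as.character(feature_names)
  if (length(feature_ids) != ncol(values))
    .stopf("feature_ids length (%d) != number of columns (%d)",
           length(feature_ids), ncol(values))
  if (length(subject_ids) != nrow(values))
    .stopf("subject_ids length (%d) != number of rows (%d)",
           length(subject_ids), nrow(values))
  if (length(feature_names) != ncol(values))
    .stopf("feature_names length must match number of features")
  if (anyDuplicated(feature_ids))
    .stopf("feature ids must be unique (duplicated: %s)",
           paste(unique(feature_ids[duplicated(feature_ids)]), collapse = ", "))
  if (anyDuplicated(subject_ids))
    .stopf("subject ids must be unique")
  if (stage %in% c("imputed", "log_normalized") && anyNA(values))
    .stopf("stage '%s' must not contain missing values", stage)
  if (stage %in% c("raw", "imputed")) {
    obs <- values[!is.na(values)]
    if (length(obs) && any(obs <= 0))
      .stopf("stage '%s' requires strictly positive intensities where present",
             stage)
  }
  dimnames(values) <- list(subject_ids, feature_ids)
  structure(list(values = values,
                 feature_ids = feature_ids,
                 feature_names = setNames(feature_names, feature_ids),
                 subject_ids = subject_ids,
                 stage = stage),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature_matrix: %d subjects x %d features [stage: %s]\n",
              nrow(x$values), ncol(x$values), x$stage))
  nmiss <- sum(is.na(x$values))
  cat(sprintf("  missing entries: %d (%.1f%%)\n", nmiss,
              100 * nmiss / length(x$values)))
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$values)

#' Subset the feature columns of a feature matrix
#'
#' @param fm a [feature_matrix()].
#' @param ids feature ids to keep, in the requested order.
#' @return a `feature_matrix` with the selected columns.
#' @export
select_features <- function(fm, ids) {
  stopifnot(inherits(fm, "feature_matrix"))
  miss <- setdiff(ids, fm$feature_ids)
  if (length(miss))
    .stopf("unknown feature ids: %s", paste(miss, collapse = ", "))
  feature_matrix(fm$values[, ids, drop = FALSE],
                 feature_ids = ids,
                 subject_ids = fm$subject_ids,
                 feature_names = unname(fm$feature_names[ids]),
                 stage = fm$stage)
}

#' Construct a clinical covariate table
#'
#' Per-subject covariates and the paired fasting glucose measurements. The
#' established risk markers used in the model comparisons are gender, waist
#' circumference, BMI, age and baseline fasting glucose.
#'
#' @param subject_ids unique subject identifiers.
#' @param gender factor or 0/1 coded gender.
#' @param waist waist circumference, cm.
#' @param bmi body mass index, kg/m^2.
#' @param age age at baseline, years.
#' @param glucose_baseline baseline fasting glucose, mg/dl.
#' @param glucose_followup follow-up fasting glucose, mg/dl.
#' @param elapsed_years time between measurements, years (> 0).
#' @return a `data.frame` of class `clinical_table`.
#' @export
clinical_table <- function(subject_ids, gender, waist, bmi, age,
                           glucose_baseline, glucose_followup, elapsed_years) {
  subject_ids <- as.character(subject_ids)
  if (anyDuplicated(subject_ids)) .stopf("subject ids must be unique")
  df <- data.frame(subject_id = subject_ids,
                   gender = gender,
                   waist = as.numeric(waist),
                   bmi = as.numeric(bmi),
                   age = as.numeric(age),
                   glucose_baseline = as.numeric(glucose_baseline),
                   glucose_followup = as.numeric(glucose_followup),
                   elapsed_years = as.numeric(elapsed_years),
                   stringsAsFactors = FALSE)
  bad <- df$subject_id[!is.finite(df$elapsed_years) | df$elapsed_years <= 0]
  if (length(bad))
    .stopf("elapsed_years must be > 0 (violated for subject(s): %s)",
           paste(head(bad, 5), collapse = ", "))
  if (any(df$glucose_baseline <= 0) || any(df$glucose_followup <= 0))
    .stopf("glucose values must be positive")
  class(df) <- c("clinical_table", "data.frame")
  df
}

#' Encode clinical covariates as a numeric predictor matrix
#'
#' Gender is encoded 0/1 (alphabetically first level = 0, or kept as-is when
#' already numeric); the remaining established markers enter untransformed.
#'
#' @param clinical a [clinical_table()].
#' @return numeric matrix with columns `gender`, `waist`, `bmi`, `age`,
#'   `glucose_baseline`, rows named by subject id.
#' @export
encode_clinical <- function(clinical) {
  stopifnot(inherits(clinical, "clinical_table"))
  g <- clinical$gender
  g <- if (is.numeric(g)) as.numeric(g) else as.numeric(factor(g)) - 1
  m <- cbind(gender = g,
             waist = clinical$waist,
             bmi = clinical$bmi,
             age = clinical$age,
             glucose_baseline = clinical$glucose_baseline)
  rownames(m) <- clinical$subject_id
  m
}

#' Write / read a feature matrix as delimited text
#'
#' Tab-separated, subjects in rows, a header row of feature ids and an
#' optional second header row of display names; empty cells encode missing
#' (below limit of detection) entries.
#'
#' @param fm a [feature_matrix()].
#' @param path file path.
#' @return `write_feature_matrix()` returns `path` invisibly;
#'   `read_feature_matrix()` returns a `feature_matrix`.
#' @export
write_feature_matrix <- function(fm, path) {
  stopifnot(inherits(fm, "feature_matrix"))
  df <- as.data.frame(fm$values)
  out <- cbind(subject_id = fm$subject_ids, df)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("subject_id", fm$feature_ids), collapse = "\t"), con)
  writeLines(paste(c("#name", unname(fm$feature_names)), collapse = "\t"), con)
  utils::write.table(out, con, sep = "\t", na = "", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @param stage processing stage to tag the matrix with on read.
#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path, stage = "raw") {
  hdr <- readLines(path, n = 2L)
  ids <- strsplit(hdr[1], "\t", fixed = TRUE)[[1]][-1]
  has_names <- startsWith(hdr[2], "#name")
  nms <- if (has_names) strsplit(hdr[2], "\t", fixed = TRUE)[[1]][-1] else ids
  df <- utils::read.delim(path, skip = if (has_names) 2L else 1L,
                          header = FALSE, sep = "\t", na.strings = "",
                          stringsAsFactors = FALSE)
  subj <- as.character(df[[1]])
  vals <- as.matrix(df[, -1, drop = FALSE])
  feature_matrix(vals, feature_ids = ids, subject_ids = subj,
                 feature_names = nms, stage = stage)
}

#' Write / read a clinical table as delimited text
#'
#' @param clinical a [clinical_table()].
#' @param path file path.
#' @export
write_clinical_table <- function(clinical, path) {
  stopifnot(inherits(clinical, "clinical_table"))
  utils::write.table(as.data.frame(clinical), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_clinical_table
#' @export
read_clinical_table <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  clinical_table(df$subject_id, df$gender, df$waist, df$bmi, df$age,
                 df$glucose_baseline, df$glucose_followup, df$elapsed_years)
}
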
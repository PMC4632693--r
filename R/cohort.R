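#' Cohort tables
#'
#' A cohort is a data frame with one row per participant and canonical
#' columns: `subject_id` (character, unique), `group` (`"HC"` or `"MS"`),
#' `age_years`, `sex` (`"F"`/`"M"`), `icv_mm3`, `putamen_left_mm3`,
#' `putamen_right_mm3`, and the patient-only columns
#' `disease_duration_months`, `edss`, `lesion_t1_ml`, `lesion_flair_ml`
#' (all `NA` for controls). Canonical internal units are mm^3 for volumes
#' and intracranial volume, years for age, months for disease duration
#' (time from first symptom manifestation to MRI), and mL for white-matter
#' lesion volumes; intracranial volume is converted to litres only for
#' reporting.
#'
#' @param df data frame carrying at least the mandatory columns.
#' @param provenance free-text label recording where the data came from.
#' @return An object of class `cohort` (a data frame).
#' @seealso [read_cohort_table()], [validate_cohort()]
#' @export
as_cohort <- function(df, provenance = "unspecified") {
  mandatory <- c("subject_id", "group", "age_years", "sex",
                 "icv_mm3", "putamen_left_mm3", "putamen_right_mm3")
  missing_cols <- setdiff(mandatory, names(df))
  if (length(missing_cols) > 0L) {
    stop("cohort is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  optional <- c("disease_duration_months", "edss", "lesion_t1_ml", "lesion_flair_ml")
  for (col in optional) {
    if (is.null(df[[col]])) df[[col]] <- rep(NA_real_, nrow(df))
  }
  df$subject_id <- as.character(df$subject_id)
  df$group <- normalize_group(df$group)
  df$sex <- normalize_sex(df$sex)
  num_cols <- c("age_years", "icv_mm3", "putamen_left_mm3", "putamen_right_mm3", optional)
  for (col in num_cols) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(v))
      bad <- which(!is.na(v) & v != "" & is.na(vn))
      if (length(bad) > 0L) {
        stop(sprintf("non-numeric value in column '%s' for subject '%s'",
                     col, df$subject_id[bad[1L]]), call. = FALSE)
      }
      df[[col]] <- vn
    }
  }
  df <- df[, c(mandatory, optional)]
  rownames(df) <- NULL
  structure(df, provenance = provenance, class = c("cohort", "data.frame"))
}

normalize_group <- function(x) {
  g <- toupper(trimws(as.character(x)))
  ok <- g %in% c("HC", "MS")
  if (any(!ok)) {
    stop("group must be 'HC' or 'MS'; found: ",
         paste(unique(g[!ok]), collapse = ", "), call. = FALSE)
  }
  g
}

normalize_sex <- function(x) {
  s <- tolower(trimws(as.character(x)))
  out <- ifelse(s %in% c("f", "female", "w"), "F",
         ifelse(s %in% c("m", "male"), "M", NA_character_))
  if (anyNA(out)) {
    stop("unrecognized sex code(s): ",
         paste(unique(s[is.na(out)]), collapse = ", "), call. = FALSE)
  }
  out
}

#' Read a cohort table from CSV/TSV
#'
#' Reads a delimited cohort table with a header row. Mandatory columns:
#' `subject_id, group, age_years, sex, icv, putamen_left_mm3,
#' putamen_right_mm3`. The optional `icv_unit` column (values `mm3` or
#' `L`, default `mm3`) controls conversion of `icv` into canonical mm^3.
#' Optional patient columns: `disease_duration_months`, `edss`,
#' `lesion_t1_ml`, `lesion_flair_ml`. Row order is preserved.
#'
#' @param path path to the table.
#' @param sep field separator; `NULL` (default) picks `\\t` for `.tsv`
#'   files and `,` otherwise.
#' @param icv_unit default unit for the `icv` column when no `icv_unit`
#'   column is present: `"mm3"` or `"L"`.
#' @return A [as_cohort()] object.
#' @export
read_cohort_table <- function(path, sep = NULL, icv_unit = c("mm3", "L")) {
  icv_unit <- match.arg(icv_unit)
  if (!file.exists(path)) stop("cohort table not found: ", path, call. = FALSE)
  if (is.null(sep)) sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = c("NA", ""), quote = "\"",
                          colClasses = "character")
  mandatory <- c("subject_id", "group", "age_years", "sex", "icv",
                 "putamen_left_mm3", "putamen_right_mm3")
  missing_cols <- setdiff(mandatory, names(df))
  if (length(missing_cols) > 0L) {
    stop("cohort table is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  units <- if ("icv_unit" %in% names(df)) {
    u <- tolower(trimws(df$icv_unit))
    u[is.na(u) | u == ""] <- tolower(icv_unit)
    u
  } else rep(tolower(icv_unit), nrow(df))
  if (!all(units %in% c("mm3", "l"))) {
    stop("icv_unit values must be 'mm3' or 'L'", call. = FALSE)
  }
  suppressWarnings(icv <- as.numeric(df$icv))
  bad <- which(!is.na(df$icv) & is.na(icv))
  if (length(bad) > 0L) {
    stop(sprintf("non-numeric value in column 'icv' for subject '%s'",
                 df$subject_id[bad[1L]]), call. = FALSE)
  }
  df$icv_mm3 <- ifelse(units == "l", icv * 1e6, icv)
  df$icv <- NULL
  df$icv_unit <- NULL
  if (anyDuplicated(df$subject_id)) {
    stop("duplicate subject_id: ",
         paste(unique(df$subject_id[duplicated(df$subject_id)]), collapse = ", "),
         call. = FALSE)
  }
  as_cohort(df, provenance = path)
}

#' Write a cohort table to CSV
#'
#' Writes the canonical columns with intracranial volume in mm^3 and an
#' explicit `icv_unit` column, so that reading the file back reproduces
#' the cohort.
#'
#' @param cohort a [as_cohort()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cohort_table <- function(cohort, path) {
  df <- as.data.frame(cohort)
  out <- data.frame(
    subject_id = df$subject_id, group = df$group,
    age_years = df$age_years, sex = df$sex,
    icv = df$icv_mm3, icv_unit = "mm3",
    putamen_left_mm3 = df$putamen_left_mm3,
    putamen_right_mm3 = df$putamen_right_mm3,
    disease_duration_months = df$disease_duration_months,
    edss = df$edss, lesion_t1_ml = df$lesion_t1_ml,
    lesion_flair_ml = df$lesion_flair_ml,
    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Validate a cohort against its structural invariants
#'
#' Checks range, uniqueness, and group/field-consistency rules without
#' mutating the cohort: unique subject ids; ages positive; intracranial
#' volume within the plausible human range 9e5--2.2e6 mm^3; putamen
#' volumes within 0--2e4 mm^3; controls carrying no disease-specific
#' fields; patient disease durations strictly positive (the logarithmic
#' trajectory model is undefined at zero); EDSS within 0--10; lesion
#' volumes non-negative.
#'
#' @param cohort a [as_cohort()] object.
#' @return A list with elements `pass` (logical) and `violations`
#'   (character vector, one message per violation).
#' @export
validate_cohort <- function(cohort) {
  df <- as.data.frame(cohort)
  v <- character(0)
  flag <- function(cond, fmt) {
    idx <- which(cond)
    if (length(idx) > 0L) sprintf(fmt, df$subject_id[idx]) else character(0)
  }
  dup <- unique(df$subject_id[duplicated(df$subject_id)])
  if (length(dup) > 0L) v <- c(v, sprintf("duplicate subject_id '%s'", dup))
  v <- c(v,
    flag(!is.na(df$age_years) & df$age_years <= 0,
         "subject '%s': age_years must be > 0"),
    flag(is.na(df$age_years), "subject '%s': age_years missing"),
    flag(is.na(df$icv_mm3) | df$icv_mm3 < 9e5 | df$icv_mm3 > 2.2e6,
         "subject '%s': icv_mm3 outside plausible range [9e5, 2.2e6]"),
    flag(is.na(df$putamen_left_mm3) | df$putamen_left_mm3 < 0 | df$putamen_left_mm3 > 2e4,
         "subject '%s': putamen_left_mm3 outside [0, 2e4]"),
    flag(is.na(df$putamen_right_mm3) | df$putamen_right_mm3 < 0 | df$putamen_right_mm3 > 2e4,
         "subject '%s': putamen_right_mm3 outside [0, 2e4]"))
  hc <- df$group == "HC"
  for (col in c("disease_duration_months", "edss", "lesion_t1_ml", "lesion_flair_ml")) {
    v <- c(v, flag(hc & !is.na(df[[col]]),
                   paste0("subject '%s': HC record carries ", col)))
  }
  v <- c(v,
    flag(!hc & !is.na(df$disease_duration_months) & df$disease_duration_months <= 0,
         "subject '%s': disease_duration_months must be > 0"),
    flag(!hc & !is.na(df$edss) & (df$edss < 0 | df$edss > 10),
         "subject '%s': edss outside [0, 10]"),
    flag(!hc & !is.na(df$lesion_t1_ml) & df$lesion_t1_ml < 0,
         "subject '%s': lesion_t1_ml negative"),
    flag(!hc & !is.na(df$lesion_flair_ml) & df$lesion_flair_ml < 0,
         "subject '%s': lesion_flair_ml negative"))
  list(pass = length(v) == 0L, violations = v)
}

#' @export
print.cohort <- function(x, ...) {
  counts <- table(factor(x$group, levels = c("HC", "MS")))
  cat(sprintf("<cohort> %d participants (%d HC, %d MS); source: %s\n",
              nrow(x), counts[["HC"]], counts[["MS"]],
              attr(x, "provenance") %||% "unspecified"))
  NextMethod()
}

`%||%` <- function(a, b) if (is.null(a)) b else a
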
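#' Pearson product-moment correlation with two-sided p
#'
#' The generic correlation utility of the pipeline; p comes from the
#' t-transform of r with n - 2 degrees of freedom.
#'
#' @param x,y numeric vectors of equal length, n >= 3, each with
#'   nonzero variance. Pairs with missing values are dropped.
#' @return A list with `r`, `n`, `p_value`.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) stop("n >= 3 required", call. = FALSE)
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("zero variance in x or y", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), n = length(x), p_value = ct$p.value)
}

#' Correlate deviation scores with white-matter lesion burden
#'
#' Pearson correlations between each patient's age-corrected deviation
#' (delta-RPV percent) and the T1w and FLAIR lesion volumes, on the raw
#' (untransformed) values.
#'
#' @param scores the deviation table from [score_cohort()].
#' @param cohort the scored [as_cohort()] object carrying lesion
#'   columns.
#' @return A data frame with one row per lesion measure: `measure`,
#'   `r`, `n`, `p_value`.
#' @export
lesion_associations <- function(scores, cohort) {
  df <- merge(scores[, c("subject_id", "delta_rpv_percent")],
              as.data.frame(cohort)[, c("subject_id", "group",
                                        "lesion_t1_ml", "lesion_flair_ml")],
              by = "subject_id", sort = FALSE)
  df <- df[df$group == "MS", , drop = FALSE]
  rows <- lapply(c(lesion_t1_ml = "lesion_t1_ml",
                   lesion_flair_ml = "lesion_flair_ml"), function(col) {
    ok <- !is.na(df[[col]])
    if (sum(ok) < 3L) {
      return(data.frame(measure = col, r = NA_real_, n = sum(ok),
                        p_value = NA_real_, stringsAsFactors = FALSE))
    }
    res <- pearson(df$delta_rpv_percent[ok], df[[col]][ok])
    data.frame(measure = col, r = res$r, n = res$n, p_value = res$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
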
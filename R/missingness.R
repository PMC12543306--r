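#' Screen a session table for non-random missingness
#'
#' Reports (a) the proportion of missing values per subject per variable and
#' (b) for every variable with at least one missing and one observed value,
#' the point-biserial correlation (Pearson correlation against the 0/1
#' missingness indicator) between its missingness and the observed values of
#' every other numeric variable, with the correlation test p-value. Evidence
#' of strong indicator-value correlation argues against missingness being
#' completely at random.
#'
#' @param sessions Session table (data frame) with at least a `subject_id`
#'   column and two or more variables.
#' @param variables Variables to screen; defaults to the numeric columns
#'   other than identifiers.
#' @return List of class `"missingness_report"` with `proportions` (columns
#'   `subject_id`, `variable`, `n`, `n_missing`, `prop_missing`) and
#'   `correlations` (columns `missing_variable`, `other_variable`, `r`,
#'   `p_value`, `n`); all-missing variables are flagged in `$degenerate`.
#' @export
missingness_report <- function(sessions, variables = NULL) {
  stopifnot(is.data.frame(sessions))
  ids <- c("subject_id", "dataset_id", "session_id")
  if (is.null(variables)) {
    variables <- setdiff(names(sessions)[vapply(sessions, is.numeric, TRUE)],
                         ids)
  }
  if (length(variables) < 2) stop("need >= 2 variables to screen")

  subj <- if ("subject_id" %in% names(sessions)) sessions$subject_id else "all"
  props <- do.call(rbind, lapply(unique(subj), function(s) {
    rows <- sessions[subj == s, variables, drop = FALSE]
    data.frame(
      subject_id = s,
      variable = variables,
      n = nrow(rows),
      n_missing = vapply(rows, function(x) sum(is.na(x)), integer(1)),
      prop_missing = vapply(rows, function(x) mean(is.na(x)), numeric(1)),
      row.names = NULL
    )
  }))

  degenerate <- variables[vapply(sessions[variables],
                                 function(x) all(is.na(x)), TRUE)]
  cors <- list()
  for (v in variables) {
    ind <- as.numeric(is.na(sessions[[v]]))
    if (all(ind == 0) || all(ind == 1)) next  # nothing to correlate
    for (w in setdiff(variables, v)) {
      ok <- !is.na(sessions[[w]])
      if (sum(ok) < 3 || stats::sd(ind[ok]) == 0 ||
          stats::sd(sessions[[w]][ok]) == 0) next
      ct <- stats::cor.test(ind[ok], sessions[[w]][ok])
      cors[[length(cors) + 1L]] <- data.frame(
        missing_variable = v, other_variable = w,
        r = unname(ct$estimate), p_value = ct$p.value, n = sum(ok)
      )
    }
  }
  cors <- if (length(cors)) do.call(rbind, cors) else
    data.frame(missing_variable = character(), other_variable = character(),
               r = numeric(), p_value = numeric(), n = integer())
  structure(list(proportions = props, correlations = cors,
                 degenerate = degenerate),
            class = "missingness_report")
}

#' @export
print.missingness_report <- function(x, ...) {
  cat("<missingness_report>\n")
  tot <- stats::aggregate(prop_missing ~ variable, x$proportions, mean)
  for (r in seq_len(nrow(tot))) {
    cat(sprintf("  %-12s mean missing proportion %.3f\n",
                tot$variable[r], tot$prop_missing[r]))
  }
  if (length(x$degenerate)) {
    cat("  all-missing variable(s):", paste(x$degenerate, collapse = ", "), "\n")
  }
  invisible(x)
}
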
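#' Percent error of a predicted RT against the user-defined RT
#'
#' `|predicted - user| / user * 100`, the convention of the bundled
#' reference tables (denominator is the user-defined RT). Vectorized;
#' returns `NA` where the user RT is missing.
#'
#' @param predicted,user Retention times in minutes; `user` must be positive
#'   where present.
#' @return Percent error(s).
#' @examples
#' percent_error(14.20, 13.9) # 2.158...
#' @export
percent_error <- function(predicted, user) {
  stopifnot(length(predicted) == length(user) || length(user) == 1L ||
              length(predicted) == 1L)
  if (any(!is.na(user) & user <= 0)) {
    stop("user-defined RT must be positive", call. = FALSE)
  }
  abs(predicted - user) / user * 100
}

#' Per-entry prediction report
#'
#' @param table Tibble with `lipid_name`, `rt_predicted` and `rt_user`
#'   columns (missing user RTs, e.g. not-detected species, allowed).
#' @param experiment Optional experiment label carried into the report.
#' @param mode Optional elution-mode label (`"gradient"`/`"isocratic"`).
#' @return Tibble with `pct_error` (`NA` where `rt_user` is missing) and the
#'   identifying columns; input row order preserved.
#' @export
prediction_report <- function(table, experiment = NA_character_,
                              mode = NA_character_) {
  stopifnot(all(c("lipid_name", "rt_predicted", "rt_user") %in% names(table)))
  tibble::tibble(
    experiment = experiment,
    mode = mode,
    lipid_name = table$lipid_name,
    lipid_class = if ("lipid_class" %in% names(table)) table$lipid_class
                  else NA_character_,
    role = if ("role" %in% names(table)) table$role else NA_character_,
    rt_predicted = table$rt_predicted,
    rt_user = table$rt_user,
    pct_error = percent_error(table$rt_predicted, table$rt_user)
  )
}

#' Experiment-level summary of prediction accuracy
#'
#' Mean percent error over every row with both a predicted and a
#' user-defined RT (reference rows included, matching the table-footer
#' convention), the squared Pearson correlation between the two, and the
#' number of compared rows. With fewer than two compared rows the summary is
#' suppressed (`NA` statistics).
#'
#' @param report A [prediction_report()] (or any tibble with `rt_predicted`,
#'   `rt_user`).
#' @return One-row tibble: `mean_pct_error`, `r2`, `n_compared`.
#' @export
summarize_experiment <- function(report) {
  cmp <- report[!is.na(report$rt_user) & !is.na(report$rt_predicted), ,
                drop = FALSE]
  n <- nrow(cmp)
  if (n < 2L) {
    return(tibble::tibble(mean_pct_error = NA_real_, r2 = NA_real_,
                          n_compared = n))
  }
  tibble::tibble(
    mean_pct_error = mean(percent_error(cmp$rt_predicted, cmp$rt_user)),
    r2 = stats::cor(cmp$rt_predicted, cmp$rt_user)^2,
    n_compared = n
  )
}

#' Pooled deviation statistics across experiments
#'
#' Counts of compared rows whose percent error (always recomputed from the
#' RT pair, never read from a stored column) exceeds each threshold, plus
#' the mean and median absolute RT error expressed in seconds. Rows with a
#' missing user RT (not analysed / not detected) are excluded throughout.
#'
#' @param reports One [prediction_report()] or a list of them (they are row
#'   bound).
#' @param thresholds Percent thresholds for the deviation counts (default
#'   `c(1, 2, 3)`); may be empty, in which case only the second-scale errors
#'   are returned.
#' @param mode_filter Optional `"gradient"` or `"isocratic"` to restrict the
#'   pooled rows by their `mode` column.
#' @return A list: `n_compared`, `counts` (named integer vector, one entry
#'   per threshold), `mean_abs_error_s`, `median_abs_error_s`.
#' @export
pooled_deviation_stats <- function(reports, thresholds = c(1, 2, 3),
                                   mode_filter = NULL) {
  if (is.data.frame(reports)) reports <- list(reports)
  stopifnot(length(reports) > 0)
  pooled <- dplyr::bind_rows(reports)
  if (!is.null(mode_filter)) {
    pooled <- pooled[pooled$mode %in% mode_filter, , drop = FALSE]
  }
  cmp <- pooled[!is.na(pooled$rt_user) & !is.na(pooled$rt_predicted), ,
                drop = FALSE]
  err_pct <- percent_error(cmp$rt_predicted, cmp$rt_user)
  abs_err_s <- abs(cmp$rt_predicted - cmp$rt_user) * 60
  counts <- integer(0)
  if (length(thresholds)) {
    counts <- vapply(thresholds, function(th) sum(err_pct > th), integer(1))
    names(counts) <- paste0(">", thresholds, "%")
  }
  list(
    n_compared = nrow(cmp),
    counts = counts,
    mean_abs_error_s = mean(abs_err_s),
    median_abs_error_s = stats::median(abs_err_s)
  )
}
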
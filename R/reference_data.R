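#' Bundled multi-experiment reference RT tables
#'
#' Published precursor-product transitions, predicted and user-defined
#' retention times, and percent-error cells for 26 Cer and 26 SM species
#' across four independently performed LC-MS/MS experiments: human serum,
#' human CSF and mouse liver (gradient elution) and rat brain (isocratic).
#' `is_reference` marks the rows that served as within-experiment points of
#' reference (internal standards, calibrators, quality controls). User cells
#' printed `NA` (not analysed) or `ND` (not detected, S/N < 3) are returned
#' as missing values with the token kept in the `*_status` column.
#'
#' @return A list with wide tibbles `cer` and `sm`; one column triple
#'   (`<exp>_pred`, `<exp>_user`, `<exp>_err`) plus `<exp>_status` per
#'   experiment (`serum`, `csf`, `liver`, `brain`).
#' @export
reference_rt_tables <- function() {
  read_one <- function(file) {
    path <- system.file("extdata", file, package = "sphingoRT",
                        mustWork = TRUE)
    raw <- utils::read.csv(path, colClasses = "character",
                           check.names = FALSE)
    tbl <- tibble::as_tibble(raw)
    num_cols <- setdiff(names(tbl), "lipid_name")
    for (exp in c("serum", "csf", "liver", "brain")) {
      ucol <- paste0(exp, "_user")
      tbl[[paste0(exp, "_status")]] <-
        ifelse(tbl[[ucol]] %in% c("NA", "ND"), tbl[[ucol]], "measured")
      tbl[[ucol]][tbl[[ucol]] %in% c("NA", "ND")] <- NA
    }
    for (col in num_cols) {
      if (!endsWith(col, "_status")) {
        tbl[[col]] <- suppressWarnings(as.numeric(tbl[[col]]))
      }
    }
    tbl$is_reference <- tbl$is_reference == 1
    tbl
  }
  list(cer = read_one("cer_reference_rt.csv"),
       sm = read_one("sm_reference_rt.csv"))
}

#' Elution mode of each bundled reference experiment
#'
#' @return Named character vector over `serum`, `csf`, `liver`, `brain`.
#' @export
reference_experiment_modes <- function() {
  c(serum = "gradient", csf = "gradient", liver = "gradient",
    brain = "isocratic")
}

#' Published per-experiment mean percent errors (table footers)
#'
#' @return Tibble with `lipid_class`, `experiment`, `mean_pct_error`.
#' @export
reference_footer_means <- function() {
  tibble::tibble(
    lipid_class = rep(c("Cer", "SM"), each = 4),
    experiment = rep(c("serum", "csf", "liver", "brain"), 2),
    mean_pct_error = c(0.58, 0.49, 0.28, 2.23, 0.46, 0.26, 1.09, 2.43)
  )
}

#' One bundled reference experiment as an experiment table
#'
#' Reconstructs the upload-table view of one experiment: the published
#' reference rows become Train entries (with their user-defined RT as the
#' known RT), everything else becomes Test. The full user-defined column is
#' kept as `rt_user` for evaluation, and the published tool predictions as
#' `rt_published`.
#'
#' @param lipid_class `"Cer"` or `"SM"`.
#' @param experiment One of `"serum"`, `"csf"`, `"liver"`, `"brain"`.
#' @param drop_unmeasured Drop species whose user RT is missing in this
#'   experiment (not analysed / not detected)? Default `FALSE`: they are kept
#'   as Test rows.
#' @return An [experiment_table()] with `rt_user`, `rt_published` columns and
#'   the experiment's elution mode as metadata.
#' @export
reference_experiment <- function(lipid_class = c("Cer", "SM"),
                                 experiment = c("serum", "csf", "liver",
                                                "brain"),
                                 drop_unmeasured = FALSE) {
  lipid_class <- match.arg(lipid_class)
  experiment <- match.arg(experiment)
  tabs <- reference_rt_tables()
  wide <- if (lipid_class == "Cer") tabs$cer else tabs$sm
  user <- wide[[paste0(experiment, "_user")]]
  rows <- tibble::tibble(
    lipid_name = wide$lipid_name,
    precursor_mz = wide$precursor_mz,
    product_mz = wide$product_mz,
    role = ifelse(wide$is_reference & !is.na(user), "train", "test"),
    rt_known = ifelse(wide$is_reference & !is.na(user), user, NA_real_),
    rt_user = user,
    rt_published = wide[[paste0(experiment, "_pred")]]
  )
  if ("product_mz2" %in% names(wide)) rows$product_mz2 <- wide$product_mz2
  if (drop_unmeasured) rows <- rows[!is.na(rows$rt_user), , drop = FALSE]
  experiment_table(rows, mode = reference_experiment_modes()[[experiment]])
}
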
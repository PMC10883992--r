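#' Read an experiment upload CSV
#'
#' The upload dialect is comma-separated UTF-8 with a mandatory header
#' `lipid_name, precursor_mz, product_mz, role, rt` (optional extra column
#' `product_mz2`), decimal points, and optional metadata comment lines of
#' the form `# key: value` above the header (recognised keys: `class`,
#' `mode`, `flow_rate`, `column`). Train rows must carry an RT; species
#' names are parsed and validated; duplicated species-transition rows are
#' rejected. Error messages cite the offending data row.
#'
#' @param path Path to the CSV file.
#' @return An [experiment_table()] (column `rt` becomes `rt_known`), with
#'   the metadata stored in attribute `"metadata"`.
#' @export
read_experiment_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  meta_lines <- grep("^#", lines, value = TRUE)
  metadata <- list()
  for (ml in meta_lines) {
    m <- regmatches(ml, regexec("^#\\s*([A-Za-z_ ]+?)\\s*:\\s*(.*)$", ml))[[1]]
    if (length(m) == 3L) {
      metadata[[gsub(" ", "_", tolower(m[2]))]] <- trimws(m[3])
    }
  }
  tbl <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  need <- c("lipid_name", "precursor_mz", "role")
  miss <- setdiff(need, names(tbl))
  if (length(miss)) {
    stop("missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if ("rt" %in% names(tbl) && !"rt_known" %in% names(tbl)) {
    tbl$rt_known <- tbl$rt
    tbl$rt <- NULL
  }
  key <- paste(tbl$lipid_name, tbl$precursor_mz,
               if ("product_mz" %in% names(tbl)) tbl$product_mz else "")
  dup <- which(duplicated(key))
  if (length(dup)) {
    stop("duplicate species+transition row(s): ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  mode <- tolower(metadata$mode %||% "gradient")
  if (!mode %in% c("gradient", "isocratic")) {
    stop("metadata mode must be 'gradient' or 'isocratic', got ",
         sQuote(mode), call. = FALSE)
  }
  out <- experiment_table(tbl, mode = mode)
  attr(out, "metadata") <- metadata
  out
}

#' Write an experiment table in the upload CSV dialect
#'
#' @param table An [experiment_table()] (or compatible tibble).
#' @param path Output path.
#' @param metadata Optional named list written as `# key: value` comment
#'   lines; the table's mode is always recorded.
#' @return `path`, invisibly.
#' @export
write_experiment_csv <- function(table, path, metadata = list()) {
  mode <- attr(table, "mode") %||% "gradient"
  metadata$mode <- metadata$mode %||% mode
  cols <- intersect(c("lipid_name", "precursor_mz", "product_mz",
                      "product_mz2", "role", "rt_known"), names(table))
  out <- tibble::as_tibble(table)[, cols]
  names(out)[names(out) == "rt_known"] <- "rt"
  out$role <- ifelse(out$role == "train", "Train", "Test")
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  for (k in names(metadata)) {
    writeLines(sprintf("# %s: %s", k, metadata[[k]]), con)
  }
  utils::write.csv(out, con, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a candidate-peak list CSV
#'
#' @param path CSV with columns `rt`, `intensity`, `snr`.
#' @return Tibble of peak candidates.
#' @export
read_peaks_csv <- function(path) {
  tbl <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  miss <- setdiff(c("rt", "intensity", "snr"), names(tbl))
  if (length(miss)) {
    stop("peak list is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (any(tbl$rt <= 0) || any(tbl$intensity < 0)) {
    stop("peak rt must be positive and intensity non-negative",
         call. = FALSE)
  }
  tbl
}

.fmt_num <- function(x, digits = 2) {
  ifelse(is.na(x), "", formatC(x, format = "f", digits = digits))
}

#' Write the output bundle of a prediction run
#'
#' Writes, under `out_dir`: `rt_list.csv` (every species including the
#' references, predicted RT at the 2-decimal print precision plus a
#' full-precision companion column), `report.csv` (the per-entry prediction
#' report, when given), `mret_profile.csv` (points and trendline
#' coefficients), `mret_plot.pdf` and `run_log.txt` (config echo and seed;
#' no timestamps, so repeated runs are byte-identical). RT unit is minutes
#' throughout.
#'
#' @param table A predicted experiment table (from [predict_experiment()]).
#' @param report Optional [prediction_report()].
#' @param profile Optional `mret_profile`; built from `table` by default.
#' @param out_dir Output directory (created if needed).
#' @param seed Seed echoed into the run log.
#' @param config Optional named list echoed into the run log.
#' @param plot Write the MRET plot PDF? Default `TRUE`.
#' @return Named character vector of the files written, invisibly.
#' @export
write_outputs <- function(table, report = NULL, profile = NULL, out_dir,
                          seed = NA_integer_, config = list(), plot = TRUE) {
  if (!"rt_predicted" %in% names(table)) {
    stop("table carries no rt_predicted; run predict_experiment() first",
         call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- c()
  rt_list <- tibble::tibble(
    lipid_name = table$lipid_name,
    precursor_mz = table$precursor_mz,
    role = ifelse(table$role == "train", "Train", "Test"),
    rt_predicted_min = .fmt_num(table$rt_predicted, 2),
    rt_predicted_full = table$rt_predicted
  )
  f <- file.path(out_dir, "rt_list.csv")
  utils::write.csv(rt_list, f, row.names = FALSE, quote = FALSE, na = "")
  files["rt_list"] <- f
  if (!is.null(report)) {
    f <- file.path(out_dir, "report.csv")
    utils::write.csv(report, f, row.names = FALSE, quote = FALSE, na = "")
    files["report"] <- f
  }
  if (is.null(profile)) profile <- build_mret_profile(table)
  prof_tbl <- dplyr::left_join(
    profile$points,
    profile$trendlines,
    by = c("lipid_class", "group")
  )
  f <- file.path(out_dir, "mret_profile.csv")
  utils::write.csv(prof_tbl, f, row.names = FALSE, quote = FALSE, na = "")
  files["mret_profile"] <- f
  if (isTRUE(plot)) {
    f <- file.path(out_dir, "mret_plot.pdf")
    grDevices::pdf(f, width = 7, height = 5)
    print(plot_mret_profile(profile))
    grDevices::dev.off()
    files["mret_plot"] <- f
  }
  f <- file.path(out_dir, "run_log.txt")
  log_lines <- c(
    "sphingoRT prediction run",
    paste0("seed: ", seed),
    paste0("mode: ", attr(table, "mode") %||% "unknown"),
    paste0("n_species: ", nrow(table)),
    paste0("n_train: ", sum(table$role == "train")),
    vapply(names(config), function(k) {
      paste0("config ", k, ": ", paste(format(config[[k]]), collapse = " "))
    }, character(1))
  )
  writeLines(log_lines, f)
  files["run_log"] <- f
  invisible(files)
}
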
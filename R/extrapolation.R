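#' Assemble and validate an experiment table
#'
#' An experiment table holds one LC-MS/MS run's sphingolipid species with
#' their Train/Test roles: Train rows are within-experiment references
#' (internal standards, calibrators, quality controls) with known RTs; Test
#' rows are the unknowns whose RTs are extrapolated.
#'
#' @param rows Tibble with at least `lipid_name`, `precursor_mz`, `role`
#'   (case-insensitive `"Train"`/`"Test"`) and `rt_known` (minutes) for Train
#'   rows; structural columns are derived from `lipid_name` when absent.
#'   Optional columns `product_mz`, `product_mz2` are carried through.
#' @param mode Elution mode metadata, `"gradient"` or `"isocratic"`; does not
#'   change the estimator, but is carried for reporting and generation.
#' @return A tibble of class `experiment_table` with parsed structural
#'   columns and an attribute `mode`.
#' @export
experiment_table <- function(rows, mode = c("gradient", "isocratic")) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(rows))
  need <- c("lipid_name", "precursor_mz", "role")
  miss <- setdiff(need, names(rows))
  if (length(miss)) {
    stop("experiment table is missing columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  tbl <- tibble::as_tibble(rows)
  if (!"rt_known" %in% names(tbl)) tbl$rt_known <- NA_real_
  tbl$role <- tolower(trimws(as.character(tbl$role)))
  bad_role <- which(!tbl$role %in% c("train", "test"))
  if (length(bad_role)) {
    stop("invalid role token at row(s) ",
         paste(bad_role, collapse = ", "),
         " (expected 'Train' or 'Test')", call. = FALSE)
  }
  if (!all(c("lipid_class", "base_unsat", "acyl_carbons",
             "acyl_unsat") %in% names(tbl))) {
    parsed <- lapply(seq_len(nrow(tbl)), function(i) {
      sp <- tryCatch(parse_lipid_name(tbl$lipid_name[i]), error = function(e) {
        stop("row ", i, ": ", conditionMessage(e), call. = FALSE)
      })
      as_tibble.lipid_species(sp)[, c("lipid_class", "backbone_hydroxyls",
                                      "base_carbons", "base_unsat",
                                      "acyl_carbons", "acyl_unsat")]
    })
    tbl <- dplyr::bind_cols(tbl, dplyr::bind_rows(parsed))
  }
  no_rt <- which(tbl$role == "train" &
                   (is.na(tbl$rt_known) | tbl$rt_known <= 0))
  if (length(no_rt)) {
    stop("Train row(s) without a positive rt_known: row(s) ",
         paste(no_rt, collapse = ", "), call. = FALSE)
  }
  attr(tbl, "mode") <- mode
  class(tbl) <- c("experiment_table", class(tbl))
  tbl
}

#' Predict retention times for one experiment
#'
#' The core extrapolation: the model family, penalty and feature recipe are
#' fixed offline per lipid class (Cer: lasso alpha = 0.001; SM: ridge
#' alpha = 0.4), while the numeric fit is re-estimated on the experiment's
#' Train references at prediction time. All rows, references included,
#' receive a predicted RT; output order equals input order. At least two
#' Train rows are required; with fewer than `min_full_train` references the
#' design is restricted to `{intercept, mass, mass_sq}` so that two or three
#' points still anchor a sensible curve.
#'
#' @param table An [experiment_table()] (or tibble accepted by it). All rows
#'   must belong to one class family (Cer or SM; HexCer rides along as an
#'   auxiliary class).
#' @param class_spec A [regression_spec()]; defaults to the class's refit
#'   default ([default_class_spec()]).
#' @param refit_features `"numeric"` (default): mass transforms plus raw
#'   structure counts, the recipe that extrapolates stably from a handful of
#'   references; `"full"` adds the one-hot blocks (useful only when
#'   reference sets are large enough for levels to repeat).
#' @param min_full_train Minimum Train rows for the chosen recipe; below it
#'   the design is restricted to `{intercept, mass, mass_sq}` (default 4).
#' @return The table with an `rt_predicted` column; the fitted model is
#'   attached as attribute `"model"`.
#' @export
predict_experiment <- function(table, class_spec = NULL,
                               refit_features = c("numeric", "full"),
                               min_full_train = 4L) {
  refit_features <- match.arg(refit_features)
  if (!inherits(table, "experiment_table")) {
    table <- experiment_table(table)
  }
  classes <- unique(table$lipid_class)
  primary <- setdiff(classes, "HexCer")
  if (length(primary) > 1L) {
    stop("experiment mixes lipid class families (",
         paste(primary, collapse = ", "),
         "); predict Cer and SM tables separately", call. = FALSE)
  }
  if (length(primary) == 0L) primary <- "HexCer"
  if (is.null(class_spec)) class_spec <- default_class_spec(primary)
  train <- table[table$role == "train", , drop = FALSE]
  if (nrow(train) < 2L) {
    stop("at least two Train references are required to extrapolate ",
         "(got ", nrow(train), ")", call. = FALSE)
  }
  vocab <- build_vocabulary(table)
  X_all <- feature_matrix(table, vocab, include_numeric = TRUE)
  if (refit_features == "numeric") {
    cols <- c("mass", "mass_sq", "mass_sqrt", "mass_log",
              "acyl_carbons", "acyl_unsat", "base_unsat")
    # headgroup block only matters when classes are mixed (HexCer auxiliary)
    if (length(classes) > 1L) {
      cols <- c(cols, grep("^ohe_head_", colnames(X_all), value = TRUE))
    }
    X_all <- X_all[, cols, drop = FALSE]
  }
  if (nrow(train) < min_full_train) {
    X_all <- X_all[, c("mass", "mass_sq"), drop = FALSE]
  }
  idx_train <- which(table$role == "train")
  model <- fit_rt_model(X_all[idx_train, , drop = FALSE],
                        table$rt_known[idx_train], class_spec)
  out <- table
  out$rt_predicted <- predict(model, X_all)
  attr(out, "model") <- model
  attr(out, "mode") <- attr(table, "mode")
  class(out) <- unique(c("experiment_table", class(out)))
  out
}

#' Build the MRET profile of a predicted experiment
#'
#' Mass versus relative elution time (MRET) profiling organises predicted
#' species into 2-D (precursor m/z, RT) points, grouped by lipid class and
#' structural unsaturation variant (`d18:U/XX:V`), with a second-order
#' polynomial trendline `rt = a + b*mz + c*mz^2` fitted to every group with
#' at least three points.
#'
#' @param table An experiment table carrying `rt_predicted` (from
#'   [predict_experiment()]); `rt` column from a user table also accepted.
#' @return An object of class `mret_profile`: list with tibbles `points`
#'   (class, group, lipid_name, precursor_mz, rt) and `trendlines` (class,
#'   group, n_points, a, b, c; coefficient rows only for groups with >= 3
#'   points).
#' @export
build_mret_profile <- function(table) {
  stopifnot(is.data.frame(table))
  rt <- if ("rt_predicted" %in% names(table)) {
    table$rt_predicted
  } else if ("rt" %in% names(table)) {
    table$rt
  } else {
    stop("table carries neither rt_predicted nor rt", call. = FALSE)
  }
  pts <- tibble::tibble(
    lipid_class = table$lipid_class,
    group = sprintf("d18:%d/XX:%d", table$base_unsat, table$acyl_unsat),
    lipid_name = table$lipid_name,
    precursor_mz = table$precursor_mz,
    rt = rt
  )
  trends <- pts |>
    dplyr::group_by(.data$lipid_class, .data$group) |>
    dplyr::group_modify(function(d, key) {
      if (nrow(d) < 3L) {
        return(tibble::tibble(n_points = nrow(d), a = NA_real_,
                              b = NA_real_, c = NA_real_))
      }
      fit <- stats::lm(rt ~ precursor_mz + I(precursor_mz^2), data = d)
      co <- stats::coef(fit)
      tibble::tibble(n_points = nrow(d), a = unname(co[1]),
                     b = unname(co[2]), c = unname(co[3]))
    }) |>
    dplyr::ungroup()
  structure(list(points = pts, trendlines = trends), class = "mret_profile")
}

#' @export
print.mret_profile <- function(x, ...) {
  cat("<mret_profile> ", nrow(x$points), " species in ",
      nrow(x$trendlines), " unsaturation groups (",
      sum(!is.na(x$trendlines$a)), " with trendlines)\n", sep = "")
  invisible(x)
}

#' Plot an MRET profile
#'
#' @param profile An `mret_profile`.
#' @return A ggplot object: points per unsaturation group with the
#'   second-order polynomial trendlines overlaid.
#' @export
plot_mret_profile <- function(profile) {
  stopifnot(inherits(profile, "mret_profile"))
  pts <- profile$points
  curves <- profile$trendlines |>
    dplyr::filter(!is.na(.data$a)) |>
    dplyr::group_by(.data$lipid_class, .data$group) |>
    dplyr::group_modify(function(d, key) {
      rng <- range(pts$precursor_mz[pts$group == key$group &
                                      pts$lipid_class == key$lipid_class])
      mz <- seq(rng[1], rng[2], length.out = 50)
      tibble::tibble(precursor_mz = mz,
                     rt = d$a + d$b * mz + d$c * mz^2)
    }) |>
    dplyr::ungroup()
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$precursor_mz, y = .data$rt,
                                    colour = .data$group)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_line(data = curves, linewidth = 0.4) +
    ggplot2::labs(x = "precursor m/z (Th)", y = "retention time (min)",
                  colour = "variant") +
    ggplot2::theme_minimal()
}
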
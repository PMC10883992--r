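#' Plan a reference-sensitivity scan
#'
#' The scan measures prediction accuracy as a function of the number and
#' structural type of reference RTs: the variant axis adds sphingoid-base /
#' acyl unsaturation variants in the given order, the chain axis adds
#' fatty-acyl chain lengths per variant, and each grid cell is averaged over
#' random draws of the chain lengths. The internal-control species is
#' retained as a reference in every draw.
#'
#' @param variant_axis Ordered variant labels (default the five canonical
#'   ones: `d18:0/XX:0`, `d18:1/XX:0`, `d18:1/XX:1`, `d18:2/XX:0`,
#'   `d18:2/XX:1`).
#' @param chain_axis Maximum number of chain lengths per variant; `NULL`
#'   (default) uses all available in the table.
#' @param n_repeats Random draws per cell (default 20).
#' @param seed Integer seed.
#' @param always_keep Lipid name of the internal-control species, always kept
#'   as a reference.
#' @return A list of class `sampling_plan`.
#' @export
sampling_plan <- function(variant_axis = c("d18:0/XX:0", "d18:1/XX:0",
                                           "d18:1/XX:1", "d18:2/XX:0",
                                           "d18:2/XX:1"),
                          chain_axis = NULL, n_repeats = 20L, seed = 1L,
                          always_keep = NULL) {
  stopifnot(n_repeats >= 1L, length(variant_axis) >= 1L)
  structure(
    list(variant_axis = variant_axis,
         chain_axis = if (is.null(chain_axis)) NULL else as.integer(chain_axis),
         n_repeats = as.integer(n_repeats), seed = as.integer(seed),
         always_keep = always_keep),
    class = "sampling_plan"
  )
}

.variant_label <- function(base_unsat, acyl_unsat) {
  sprintf("d18:%d/XX:%d", base_unsat, acyl_unsat)
}

#' Scan prediction accuracy over reference subsets
#'
#' For each cell `(n_chains, n_variants)` of the plan grid, draws
#' `n_repeats` random reference subsets consisting of the first `n_variants`
#' variants of the axis with `n_chains` randomly chosen chain lengths each
#' (plus the internal control), runs [predict_experiment()] with those rows
#' as Train, and averages the percent error of the withheld species against
#' their user RTs. When a draw leaves no withheld species (the exhaustive
#' subset), the cell scores the fitted values of all species instead. Cells
#' that cannot supply two references are marked unavailable.
#'
#' @param full_table An [experiment_table()] (or tibble) with a user RT for
#'   every species in column `rt_user` (rows with missing `rt_user` are
#'   dropped).
#' @param plan A [sampling_plan()]; its `always_keep` species must be in the
#'   table.
#' @param class_spec Optional [regression_spec()] passed to the predictor.
#' @return Tibble of class `sensitivity_grid`: one row per cell with
#'   `n_chains`, `n_variants`, `mean_pct_error`, `sd_pct_error`, `n_refs`,
#'   `available` and `accept` (mean error < 3%).
#' @export
sensitivity_scan <- function(full_table, plan = sampling_plan(),
                             class_spec = NULL) {
  stopifnot(inherits(plan, "sampling_plan"))
  if (!inherits(full_table, "experiment_table")) {
    full_table <- experiment_table(full_table)
  }
  mode <- attr(full_table, "mode")
  if (!"rt_user" %in% names(full_table)) {
    stop("full_table must carry user RTs in column rt_user", call. = FALSE)
  }
  tbl <- tibble::as_tibble(full_table)[!is.na(full_table$rt_user), ,
                                       drop = FALSE]
  tbl$variant <- .variant_label(tbl$base_unsat, tbl$acyl_unsat)
  control <- plan$always_keep
  if (!is.null(control) && !control %in% tbl$lipid_name) {
    stop("internal control ", sQuote(control), " is not in the table",
         call. = FALSE)
  }
  frame <- tbl[is.null(control) | tbl$lipid_name != control, , drop = FALSE]
  variants <- intersect(plan$variant_axis, unique(frame$variant))
  chains_by_variant <- split(frame$lipid_name, frame$variant)
  max_chains <- plan$chain_axis %||%
    max(vapply(chains_by_variant[variants], length, integer(1)))
  cells <- expand.grid(n_chains = seq_len(max_chains),
                       n_variants = seq_along(variants))
  out <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    nc <- cells$n_chains[i]
    nv <- cells$n_variants[i]
    errs <- numeric(plan$n_repeats)
    n_refs <- NA_integer_
    ok <- TRUE
    for (r in seq_len(plan$n_repeats)) {
      cell_seed <- (plan$seed + 7919L * nv + 104729L * nc + r) %%
        .Machine$integer.max
      refs <- .with_seed(cell_seed, {
        unlist(lapply(variants[seq_len(nv)], function(v) {
          pool <- chains_by_variant[[v]]
          sample(pool, size = min(nc, length(pool)))
        }), use.names = FALSE)
      })
      refs <- union(control, refs)
      if (length(refs) < 2L) {
        ok <- FALSE
        break
      }
      n_refs <- length(refs)
      run <- tbl
      run$role <- ifelse(run$lipid_name %in% refs, "train", "test")
      run$rt_known <- ifelse(run$role == "train", run$rt_user, NA_real_)
      run_tbl <- experiment_table(run, mode = mode)
      pred <- predict_experiment(run_tbl, class_spec = class_spec)
      withheld <- pred[pred$role == "test", , drop = FALSE]
      scored <- if (nrow(withheld)) withheld else pred
      errs[r] <- mean(percent_error(scored$rt_predicted, scored$rt_user))
    }
    out[[i]] <- tibble::tibble(
      n_chains = nc, n_variants = nv,
      variants = paste(variants[seq_len(nv)], collapse = ";"),
      mean_pct_error = if (ok) mean(errs) else NA_real_,
      sd_pct_error = if (ok) stats::sd(errs) else NA_real_,
      n_refs = n_refs,
      available = ok,
      accept = ok && mean(errs) < 3
    )
  }
  res <- dplyr::bind_rows(out)
  attr(res, "plan") <- plan
  class(res) <- c("sensitivity_grid", class(res))
  res
}

#' Plot a sensitivity grid as a heat map
#'
#' @param grid A `sensitivity_grid` from [sensitivity_scan()].
#' @param accept_threshold Percent error drawn as the acceptance contour
#'   colour midpoint (default 3).
#' @return A ggplot object.
#' @export
plot_sensitivity_grid <- function(grid, accept_threshold = 3) {
  stopifnot(inherits(grid, "sensitivity_grid"))
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$n_variants,
                                     y = .data$n_chains,
                                     fill = .data$mean_pct_error)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.1f", .data$mean_pct_error)), size = 3) +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick",
                                  midpoint = accept_threshold) +
    ggplot2::labs(x = "structural variants (references)",
                  y = "fatty-acyl chain lengths per variant",
                  fill = "mean % error") +
    ggplot2::theme_minimal()
}
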
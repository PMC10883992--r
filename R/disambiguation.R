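# natural abundance of 13C
.P_C13 <- 0.0107

#' Carbon isotopologue pattern of a species
#'
#' Relative abundances of the M, M+1 and M+2 isotopologues under a binomial
#' model of 13C incorporation (natural abundance p = 0.0107), normalised to
#' the monoisotopic peak: `abundance(k) = C(n,k) (p/(1-p))^k`. Heavy H/N/O
#' contributions (< 15% of the M+1 of these lipids) are deliberately
#' omitted; the pattern is used qualitatively for interference flagging.
#'
#' @param carbon_count Number of carbon atoms, >= 0.
#' @return A list of class `isotope_pattern` with `offsets` (0:2),
#'   `abundances` (first element 1) and `carbon_count`.
#' @examples
#' isotope_pattern(41)$abundances[2] # ~0.4435
#' @export
isotope_pattern <- function(carbon_count) {
  carbon_count <- as.integer(carbon_count)
  if (is.na(carbon_count) || carbon_count < 0L) {
    stop("carbon_count must be a non-negative integer", call. = FALSE)
  }
  n <- carbon_count
  r <- .P_C13 / (1 - .P_C13)
  abundances <- c(1, n * r, n * (n - 1) / 2 * r^2)
  structure(
    list(offsets = 0:2, abundances = abundances, carbon_count = n),
    class = "isotope_pattern"
  )
}

#' @export
print.isotope_pattern <- function(x, ...) {
  cat("<isotope_pattern> n_C=", x$carbon_count, ": M=1, M+1=",
      signif(x$abundances[2], 4), ", M+2=", signif(x$abundances[3], 4),
      "\n", sep = "")
  invisible(x)
}

# structure-level species grid searched for isobars: d18:0/1/2 backbones,
# acyl chains 12-26 carbons with 0-1 C=C, Cer/SM/HexCer headgroups
.modeled_species_grid <- function(classes = c("Cer", "SM", "HexCer"),
                                  acyl_carbons = 12:26, acyl_unsat = 0:1,
                                  base_unsat = 0:2) {
  grid <- expand.grid(lipid_class = classes, base_unsat = base_unsat,
                      acyl_carbons = acyl_carbons, acyl_unsat = acyl_unsat,
                      stringsAsFactors = FALSE)
  species <- lapply(seq_len(nrow(grid)), function(i) {
    lipid_species(grid$lipid_class[i], "d", 18L, grid$base_unsat[i],
                  grid$acyl_carbons[i], grid$acyl_unsat[i])
  })
  grid$lipid_name <- vapply(species, compose_lipid_name, character(1))
  grid$precursor_mz <- vapply(species, precursor_mz_calc, numeric(1))
  tibble::as_tibble(grid)
}

# does a species produce the given product ion?
.species_matches_product <- function(grid, product_mz, tolerance) {
  frag <- .BACKBONE_FRAGMENTS$fragment_mz[
    match(grid$base_unsat, .BACKBONE_FRAGMENTS$base_unsat)]
  backbone_hit <- abs(frag - product_mz) <= tolerance
  headgroup_hit <- grid$lipid_class == "SM" &
    abs(.SM_HEADGROUP_MZ - product_mz) <= tolerance
  backbone_hit | headgroup_hit
}

#' Enumerate isobaric candidates of an MRM transition
#'
#' Searches the modelled species grid (d18:0/1/2 backbones, acyl chains
#' 12-26 carbons with 0-1 C=C) for species whose `[M+H]+` and product ion
#' both match the transition within tolerance. When RT predictions are
#' supplied the candidates are ranked by MRET plausibility (proximity of the
#' predicted RT to `rt_observed`, if given, else by predicted RT).
#'
#' A lone m/z 184 product identifies only the phosphocholine headgroup;
#' a warning notes that phosphatidylcholines share this fragment.
#'
#' @param precursor_mz,product_mz The transition (Th).
#' @param class_hint Optional class restriction (`"Cer"`, `"SM"`,
#'   `"HexCer"`).
#' @param tolerance Mass tolerance in Th (default 0.5).
#' @param rt_predictions Optional tibble (`lipid_name`, `rt_predicted`) used
#'   for ranking.
#' @param rt_observed Optional observed peak RT (minutes) to rank against.
#' @return Tibble of candidate species (possibly empty), with
#'   `rt_predicted` and rank when predictions are supplied.
#' @export
enumerate_isobar_candidates <- function(precursor_mz, product_mz,
                                        class_hint = NULL, tolerance = 0.5,
                                        rt_predictions = NULL,
                                        rt_observed = NULL) {
  stopifnot(precursor_mz > 0, product_mz > 0, precursor_mz > product_mz)
  classes <- class_hint %||% c("Cer", "SM", "HexCer")
  grid <- .modeled_species_grid(classes = classes)
  hit <- abs(grid$precursor_mz - precursor_mz) <= tolerance &
    .species_matches_product(grid, product_mz, tolerance)
  out <- grid[hit, , drop = FALSE]
  if (abs(product_mz - .SM_HEADGROUP_MZ) <= tolerance) {
    warning("m/z 184 identifies only the choline headgroup; ",
            "phosphatidylcholine ions share this fragment", call. = FALSE)
  }
  if (!is.null(rt_predictions) && nrow(out)) {
    out <- dplyr::left_join(
      out, rt_predictions[, c("lipid_name", "rt_predicted")],
      by = "lipid_name")
    key <- if (!is.null(rt_observed)) {
      abs(out$rt_predicted - rt_observed)
    } else {
      out$rt_predicted
    }
    out <- out[order(key, out$lipid_name), , drop = FALSE]
  }
  tibble::as_tibble(out)
}

#' Flag [M+1] isotopologue interference
#'
#' A species interferes with the target transition when its monoisotopic
#' `[M+H]+` plus one mass unit matches the target precursor within the mass
#' tolerance and its predicted RT falls within `rt_tolerance` of the
#' target's. The canonical case: HexCer (d18:1/XX:0) species produce an
#' `[M+1]` ion overlapping the `[M+H]+` of SM (d18:1/XX:1).
#'
#' @param target A `lipid_species` with `precursor_mz` set (the printed
#'   transition precursor is used when present, else the computed one).
#' @param others List of `lipid_species` to screen.
#' @param rt_predictions Tibble (`lipid_name`, `rt_predicted`) covering the
#'   target and the screened species.
#' @param rt_tolerance RT window in minutes (default 0.2, the gradient
#'   default; use about 0.4 for isocratic runs).
#' @param mass_tolerance Mass window in Th (default 0.5).
#' @return Tibble of flagged species: `lipid_name`, `m1_mz`, `rt_predicted`,
#'   `delta_rt`. Zero rows when nothing interferes.
#' @export
flag_isotopologue_interference <- function(target, others, rt_predictions,
                                           rt_tolerance = 0.2,
                                           mass_tolerance = 0.5) {
  stopifnot(inherits(target, "lipid_species"))
  if (inherits(others, "lipid_species")) others <- list(others)
  target_mz <- if (!is.na(target$precursor_mz)) target$precursor_mz else
    precursor_mz_calc(target)
  target_name <- compose_lipid_name(target)
  rt_of <- function(nm) {
    i <- match(nm, rt_predictions$lipid_name)
    if (is.na(i)) NA_real_ else rt_predictions$rt_predicted[i]
  }
  target_rt <- rt_of(target_name)
  rows <- lapply(others, function(sp) {
    m1 <- precursor_mz_calc(sp) + 1
    nm <- compose_lipid_name(sp)
    rt <- rt_of(nm)
    if (is.na(rt) || is.na(target_rt)) return(NULL)
    if (abs(m1 - target_mz) <= mass_tolerance &&
        abs(rt - target_rt) <= rt_tolerance) {
      tibble::tibble(lipid_name = nm, m1_mz = m1, rt_predicted = rt,
                     delta_rt = rt - target_rt)
    } else {
      NULL
    }
  })
  flagged <- dplyr::bind_rows(rows)
  if (!nrow(flagged)) {
    flagged <- tibble::tibble(lipid_name = character(), m1_mz = numeric(),
                              rt_predicted = numeric(), delta_rt = numeric())
  }
  flagged
}

#' Assign a predicted RT to a chromatogram peak
#'
#' Candidate peaks below the signal-to-noise floor are discarded; among the
#' survivors within the RT tolerance, the peak nearest the predicted RT is
#' chosen, ties broken by higher intensity. Invariant to peak-list order.
#'
#' @param predicted_rt Predicted retention time (minutes).
#' @param peaks Tibble with columns `rt`, `intensity`, `snr`.
#' @param rt_tolerance RT window in minutes (default 0.2 gradient / use 0.4
#'   for isocratic).
#' @param snr_min Minimum signal-to-noise ratio (default 3).
#' @return The chosen peak as a one-row tibble, or `NULL` (unassigned).
#' @export
assign_peak <- function(predicted_rt, peaks, rt_tolerance = 0.2,
                        snr_min = 3) {
  stopifnot(rt_tolerance > 0, is.data.frame(peaks),
            all(c("rt", "intensity", "snr") %in% names(peaks)))
  ok <- peaks[peaks$snr >= snr_min &
                abs(peaks$rt - predicted_rt) <= rt_tolerance, , drop = FALSE]
  if (!nrow(ok)) return(NULL)
  d <- abs(ok$rt - predicted_rt)
  best <- which(d == min(d))
  if (length(best) > 1L) best <- best[which.max(ok$intensity[best])]
  tibble::as_tibble(ok[best, , drop = FALSE])
}
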
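#' Build the categorical vocabulary for feature encoding
#'
#' Collects the sorted unique levels of the categorical structure fields
#' (acyl carbon count, acyl unsaturation, backbone unsaturation, headgroup /
#' lipid class) over a set of species. The vocabulary fixes the order of the
#' one-hot blocks so that feature vectors are comparable across calls; it is
#' rebuilt per run from the union of Train and Test species so in-experiment
#' species are never silently zeroed.
#'
#' @param species_list A list of `lipid_species`, or a tibble with columns
#'   `acyl_carbons`, `acyl_unsat`, `base_unsat`, `lipid_class`.
#' @return A list of class `rt_vocabulary` with ordered integer/character
#'   level vectors `acyl_carbons`, `acyl_unsat`, `base_unsat`, `headgroup`.
#' @export
build_vocabulary <- function(species_list) {
  tbl <- .species_fields(species_list)
  if (!nrow(tbl)) stop("species_list must be non-empty", call. = FALSE)
  structure(
    list(
      acyl_carbons = sort(unique(tbl$acyl_carbons)),
      acyl_unsat = sort(unique(tbl$acyl_unsat)),
      base_unsat = sort(unique(tbl$base_unsat)),
      headgroup = sort(unique(tbl$lipid_class))
    ),
    class = "rt_vocabulary"
  )
}

.species_fields <- function(species_list) {
  if (inherits(species_list, "data.frame")) {
    stopifnot(all(c("acyl_carbons", "acyl_unsat", "base_unsat",
                    "lipid_class") %in% names(species_list)))
    return(tibble::as_tibble(species_list))
  }
  if (inherits(species_list, "lipid_species")) {
    species_list <- list(species_list)
  }
  dplyr::bind_rows(lapply(species_list, function(sp) {
    tibble::tibble(
      lipid_class = sp$lipid_class,
      base_unsat = sp$base_unsat,
      acyl_carbons = sp$acyl_carbons,
      acyl_unsat = sp$acyl_unsat,
      precursor_mz = sp$precursor_mz
    )
  }))
}

#' Engineer the regression descriptor vector of a species
#'
#' Descriptors are the mass transforms of the `[M+H]+` precursor
#' (mass, mass squared, square root and natural log of the mass), optional
#' numeric structure counts, and one-hot blocks over the vocabulary levels of
#' acyl carbon count, acyl unsaturation, backbone unsaturation and headgroup.
#' Out-of-vocabulary levels yield an all-zero block (no error); numeric
#' counts are what allow extrapolation to unseen chain lengths.
#'
#' @param species A `lipid_species` (or tibble of species fields including
#'   `precursor_mz`) with positive precursor m/z.
#' @param vocabulary An `rt_vocabulary` from [build_vocabulary()].
#' @param include_numeric Also include raw numeric counts
#'   (`acyl_carbons`, `acyl_unsat`, `base_unsat`)? Default `TRUE`.
#' @return A named numeric vector (one species) or matrix (several species,
#'   one row each) of descriptors.
#' @examples
#' sp <- parse_lipid_name("Cer (d18:1/16:0)")
#' sp$precursor_mz <- 538.6
#' engineer_features(sp, build_vocabulary(list(sp)))
#' @export
engineer_features <- function(species, vocabulary, include_numeric = TRUE) {
  stopifnot(inherits(vocabulary, "rt_vocabulary"))
  tbl <- .species_fields(species)
  if (any(is.na(tbl$precursor_mz)) || any(tbl$precursor_mz <= 0)) {
    stop("every species needs a positive precursor_mz", call. = FALSE)
  }
  mass <- tbl$precursor_mz
  blocks <- list(
    mass = mass,
    mass_sq = mass^2,
    mass_sqrt = sqrt(mass),
    mass_log = log(mass)
  )
  if (include_numeric) {
    blocks$acyl_carbons <- as.numeric(tbl$acyl_carbons)
    blocks$acyl_unsat <- as.numeric(tbl$acyl_unsat)
    blocks$base_unsat <- as.numeric(tbl$base_unsat)
  }
  X <- do.call(cbind, blocks)
  ohe <- function(values, levels, prefix) {
    out <- vapply(levels, function(l) as.numeric(values == l),
                  numeric(length(values)))
    out <- matrix(out, nrow = length(values),
                  dimnames = list(NULL, paste0(prefix, levels)))
    out
  }
  X <- cbind(
    X,
    ohe(tbl$acyl_carbons, vocabulary$acyl_carbons, "ohe_acyl_c_"),
    ohe(tbl$acyl_unsat, vocabulary$acyl_unsat, "ohe_acyl_u_"),
    ohe(tbl$base_unsat, vocabulary$base_unsat, "ohe_base_u_"),
    ohe(tbl$lipid_class, vocabulary$headgroup, "ohe_head_")
  )
  if (nrow(X) == 1L) {
    v <- X[1L, ]
    names(v) <- colnames(X)
    return(v)
  }
  X
}

#' Feature matrix for an experiment table
#'
#' @param table Tibble of species fields (e.g. an experiment table).
#' @param vocabulary An `rt_vocabulary`; defaults to the vocabulary of
#'   `table` itself.
#' @param include_numeric Passed to [engineer_features()].
#' @return Numeric matrix, one row per table row.
#' @export
feature_matrix <- function(table, vocabulary = build_vocabulary(table),
                           include_numeric = TRUE) {
  X <- engineer_features(table, vocabulary, include_numeric = include_numeric)
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L, dimnames = list(NULL, names(X)))
  X
}
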
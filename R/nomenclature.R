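#' Sphingolipid shorthand nomenclature
#'
#' Sphingolipids are named at the structure level as
#' `Class (pBB:U/AA:V)`, e.g. `"Cer (d18:1/24:0)"`: a sphingoid base with
#' `BB` carbons, `U` C=C bonds and hydroxylation prefix `p` (`m` = mono-,
#' `d` = di-, `t` = trihydroxy), amide-linked to a fatty acyl chain of `AA`
#' carbons and `V` C=C bonds. Sum-composition names such as `"SM (d36:2)"`
#' carry only the total carbon and double-bond count and are expanded into
#' their structure-level isobar candidates.
#'
#' @name nomenclature
#' @keywords internal
NULL

# hydroxylation prefix -> number of backbone hydroxyls
.HYDROXYL_LEVELS <- c(m = 1L, d = 2L, t = 3L)

# diagnostic sphingoid-base fragments of d18:X backbones ([M+H-H2O...]+ series)
.BACKBONE_FRAGMENTS <- tibble::tibble(
  fragment_mz = c(266.3, 264.3, 262.3),
  base_unsat  = c(0L, 1L, 2L)
)

# phosphocholine headgroup fragment of SM
.SM_HEADGROUP_MZ <- 184.1

#' Construct a sphingolipid species
#'
#' Low-level constructor and validator for the structural identity of one
#' ceramide (Cer), sphingomyelin (SM) or hexosylceramide (HexCer) species.
#' Most users should call [parse_lipid_name()] instead.
#'
#' @param lipid_class One of `"Cer"`, `"SM"`, `"HexCer"`.
#' @param backbone_hydroxyls Hydroxylation prefix `"m"`, `"d"` or `"t"`.
#' @param base_carbons,base_unsat Carbon count and number of C=C bonds of the
#'   sphingoid base.
#' @param acyl_carbons,acyl_unsat Carbon count and number of C=C bonds of the
#'   N-linked fatty acyl chain.
#' @param precursor_mz Optional `[M+H]+` precursor m/z (Th).
#' @param product_mzs Optional numeric vector of product-ion m/z (Th).
#' @return An object of class `lipid_species`.
#' @export
lipid_species <- function(lipid_class, backbone_hydroxyls, base_carbons,
                          base_unsat, acyl_carbons, acyl_unsat,
                          precursor_mz = NA_real_, product_mzs = numeric()) {
  lipid_class <- match.arg(lipid_class, c("Cer", "SM", "HexCer"))
  backbone_hydroxyls <- match.arg(backbone_hydroxyls, c("m", "d", "t"))
  base_carbons <- as.integer(base_carbons)
  base_unsat <- as.integer(base_unsat)
  acyl_carbons <- as.integer(acyl_carbons)
  acyl_unsat <- as.integer(acyl_unsat)
  if (is.na(base_carbons) || base_carbons < 12L || base_carbons > 22L) {
    stop("base_carbons must be an integer in [12, 22], got ", base_carbons,
         call. = FALSE)
  }
  if (is.na(base_unsat) || !base_unsat %in% 0:2) {
    stop("base_unsat must be 0, 1 or 2, got ", base_unsat, call. = FALSE)
  }
  if (is.na(acyl_carbons) || acyl_carbons < 2L) {
    stop("acyl_carbons must be an integer >= 2, got ", acyl_carbons,
         call. = FALSE)
  }
  if (is.na(acyl_unsat) || acyl_unsat < 0L) {
    stop("acyl_unsat must be a non-negative integer, got ", acyl_unsat,
         call. = FALSE)
  }
  if (length(product_mzs) && !is.na(precursor_mz) &&
      precursor_mz <= max(product_mzs)) {
    stop("precursor_mz must exceed every product m/z", call. = FALSE)
  }
  structure(
    list(
      lipid_class = lipid_class,
      backbone_hydroxyls = backbone_hydroxyls,
      base_carbons = base_carbons,
      base_unsat = base_unsat,
      acyl_carbons = acyl_carbons,
      acyl_unsat = acyl_unsat,
      precursor_mz = as.numeric(precursor_mz),
      product_mzs = as.numeric(product_mzs)
    ),
    class = "lipid_species"
  )
}

#' @export
print.lipid_species <- function(x, ...) {
  cat("<lipid_species> ", compose_lipid_name(x), "\n", sep = "")
  if (!is.na(x$precursor_mz)) {
    cat("  precursor m/z: ", x$precursor_mz, "\n", sep = "")
  }
  if (length(x$product_mzs)) {
    cat("  product m/z:   ", paste(x$product_mzs, collapse = ", "), "\n",
        sep = "")
  }
  invisible(x)
}

#' Parse a shorthand sphingolipid name
#'
#' Accepts structure-level names (`"Cer (d18:1/24:0)"`, whitespace optional)
#' and sum-composition names (`"SM (d36:2)"`). Sum compositions return a
#' species with the backbone marked undetermined and a `candidates` attribute
#' holding the structure-level isobars consistent with a d18:X backbone and an
#' acyl chain with at most one C=C (the modelled grid).
#'
#' @param name Shorthand name, e.g. `"Cer (d18:1/17:0)"`.
#' @return A `lipid_species`. For sum compositions, fields `base_carbons`,
#'   `base_unsat`, `acyl_carbons`, `acyl_unsat` are `NA` and
#'   `attr(x, "candidates")` lists candidate species.
#' @examples
#' parse_lipid_name("Cer (d18:1/17:0)")
#' parse_lipid_name("SM(d18:0/24:0)")
#' @export
parse_lipid_name <- function(name) {
  stopifnot(is.character(name), length(name) == 1L)
  raw <- name
  txt <- trimws(name)
  m <- regmatches(
    txt,
    regexec("^(\\w+)\\s*\\(\\s*([a-z]?)(\\d+)\\s*:\\s*(\\d+)\\s*(?:/\\s*(\\d+)\\s*:\\s*(\\d+)\\s*)?\\)$",
            txt)
  )[[1]]
  if (!length(m)) {
    stop("cannot parse lipid name ", sQuote(raw),
         ": expected 'Class (pBB:U/AA:V)'", call. = FALSE)
  }
  cls <- m[2]
  if (!cls %in% c("Cer", "SM", "HexCer")) {
    stop("unknown lipid class token ", sQuote(cls), " in ", sQuote(raw),
         call. = FALSE)
  }
  prefix <- m[3]
  if (!nzchar(prefix)) {
    stop("missing backbone hydroxylation prefix (m/d/t) in ", sQuote(raw),
         call. = FALSE)
  }
  if (!prefix %in% names(.HYDROXYL_LEVELS)) {
    stop("unknown hydroxylation prefix ", sQuote(prefix), " in ", sQuote(raw),
         call. = FALSE)
  }
  c1 <- as.integer(m[4])
  u1 <- as.integer(m[5])
  if (!nzchar(m[6])) {
    # sum composition, e.g. SM (d36:2): no acyl part printed
    if (c1 <= 22L) {
      stop("missing fatty-acyl component in ", sQuote(raw),
           ": structure-level names require 'BB:U/AA:V'", call. = FALSE)
    }
    return(.sum_composition_species(cls, prefix, c1, u1, raw))
  }
  c2 <- as.integer(m[6])
  u2 <- as.integer(m[7])
  lipid_species(cls, prefix, c1, u1, c2, u2)
}

# Expand Class (dNN:U) into structure-level candidates: d18:X backbones with
# X in 0..2 and acyl unsaturation restricted to 0..1 (the modelled grid).
.sum_composition_species <- function(cls, prefix, total_c, total_u, raw) {
  if (prefix != "d") {
    stop("only dihydroxy (d) backbones are modelled for sum composition ",
         sQuote(raw), call. = FALSE)
  }
  acyl_c <- total_c - 18L
  if (acyl_c < 2L) {
    stop("sum composition ", sQuote(raw),
         " is incompatible with a d18:X backbone", call. = FALSE)
  }
  cand <- list()
  for (bu in 0:2) {
    au <- total_u - bu
    if (au >= 0L && au <= 1L) {
      cand[[length(cand) + 1L]] <-
        lipid_species(cls, "d", 18L, bu, acyl_c, au)
    }
  }
  sp <- structure(
    list(
      lipid_class = cls,
      backbone_hydroxyls = prefix,
      base_carbons = NA_integer_,
      base_unsat = NA_integer_,
      acyl_carbons = NA_integer_,
      acyl_unsat = NA_integer_,
      total_carbons = total_c,
      total_unsat = total_u,
      precursor_mz = NA_real_,
      product_mzs = numeric()
    ),
    class = "lipid_species"
  )
  attr(sp, "candidates") <- cand
  sp
}

#' Compose the canonical shorthand name of a species
#'
#' Canonical form uses a single space after the class token:
#' `"Cer (d18:1/24:0)"`.
#'
#' @param species A `lipid_species`.
#' @return Character scalar.
#' @export
compose_lipid_name <- function(species) {
  stopifnot(inherits(species, "lipid_species"))
  if (is.na(species$base_carbons)) {
    return(sprintf("%s (%s%d:%d)", species$lipid_class,
                   species$backbone_hydroxyls, species$total_carbons,
                   species$total_unsat))
  }
  sprintf("%s (%s%d:%d/%d:%d)", species$lipid_class,
          species$backbone_hydroxyls, species$base_carbons,
          species$base_unsat, species$acyl_carbons, species$acyl_unsat)
}

#' Deduce the sphingoid backbone from MRM product ions
#'
#' The d18:X backbones fragment to diagnostic ions at m/z 266.3 (d18:0),
#' 264.3 (d18:1) and 262.3 (d18:2). A lone m/z 184 product identifies the
#' phosphocholine headgroup of SM but carries no backbone information.
#'
#' @param product_mzs Numeric vector of product-ion m/z (Th), non-empty.
#' @param tolerance Matching tolerance in Th (default 0.5, unit resolution of
#'   a triple quadrupole).
#' @return A list with elements `backbone_hydroxyls`, `base_carbons`,
#'   `base_unsat` (all `NA` with `status = "undetermined"` when only the SM
#'   headgroup ion is seen), `status` (`"determined"`/`"undetermined"`) and
#'   `headgroup` (`"SM"` when m/z 184 is present, else `NA`).
#' @examples
#' infer_backbone_from_fragments(264.3) # d18:1
#' infer_backbone_from_fragments(184.0) # SM headgroup, backbone undetermined
#' @export
infer_backbone_from_fragments <- function(product_mzs, tolerance = 0.5) {
  stopifnot(is.numeric(product_mzs), length(product_mzs) >= 1L,
            tolerance > 0)
  hits <- .BACKBONE_FRAGMENTS[
    vapply(.BACKBONE_FRAGMENTS$fragment_mz,
           function(f) any(abs(product_mzs - f) <= tolerance), logical(1)), ]
  headgroup <- if (any(abs(product_mzs - .SM_HEADGROUP_MZ) <= tolerance)) {
    "SM"
  } else {
    NA_character_
  }
  if (nrow(hits) > 1L) {
    stop("conflicting backbone fragments nominated: ",
         paste(sprintf("m/z %.1f (d18:%d)", hits$fragment_mz,
                       hits$base_unsat), collapse = ", "),
         call. = FALSE)
  }
  if (nrow(hits) == 1L) {
    return(list(backbone_hydroxyls = "d", base_carbons = 18L,
                base_unsat = hits$base_unsat, status = "determined",
                headgroup = headgroup))
  }
  list(backbone_hydroxyls = NA_character_, base_carbons = NA_integer_,
       base_unsat = NA_integer_, status = "undetermined",
       headgroup = headgroup)
}

#' Convert species to a one-row tibble
#'
#' @param x A `lipid_species`.
#' @param ... Unused.
#' @return One-row tibble of structural fields.
#' @export
as_tibble.lipid_species <- function(x, ...) {
  tibble::tibble(
    lipid_name = compose_lipid_name(x),
    lipid_class = x$lipid_class,
    backbone_hydroxyls = x$backbone_hydroxyls,
    base_carbons = x$base_carbons,
    base_unsat = x$base_unsat,
    acyl_carbons = x$acyl_carbons,
    acyl_unsat = x$acyl_unsat,
    precursor_mz = x$precursor_mz
  )
}
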
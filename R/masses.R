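# Monoisotopic element masses (u) and the proton mass used for [M+H]+.
.ELEMENT_MASS <- c(
  C = 12.0,
  H = 1.00782503207,
  N = 14.0030740048,
  O = 15.9949146196,
  P = 30.97376163
)
.PROTON_MASS <- 1.007276467

#' Molecular formula of a sphingolipid species
#'
#' Formula templates per class, for a base of `B` carbons / `U` C=C and an
#' acyl chain of `A` carbons / `V` C=C (`n = B + A`, `u = U + V`):
#' * Cer: `C(n) H(2n+1-2u) N O3`
#' * SM: `C(n+5) H(2n+13-2u) N2 O6 P` (phosphocholine headgroup)
#' * HexCer: `C(n+6) H(2n+11-2u) N O8` (hexose headgroup)
#'
#' Only dihydroxy (d) backbones are covered; these templates reproduce the
#' printed precursor m/z of the bundled reference tables within 0.5 Th.
#'
#' @param species A `lipid_species` with structure-level fields set.
#' @return Named integer vector of element counts (C, H, N, O, P).
#' @export
molecular_formula <- function(species) {
  stopifnot(inherits(species, "lipid_species"))
  if (is.na(species$base_carbons)) {
    stop("molecular_formula() needs a structure-level species, not a sum ",
         "composition", call. = FALSE)
  }
  if (species$backbone_hydroxyls != "d") {
    stop("formula templates cover dihydroxy (d) backbones only",
         call. = FALSE)
  }
  n <- species$base_carbons + species$acyl_carbons
  u <- species$base_unsat + species$acyl_unsat
  switch(species$lipid_class,
    Cer = c(C = n, H = 2L * n + 1L - 2L * u, N = 1L, O = 3L, P = 0L),
    SM = c(C = n + 5L, H = 2L * n + 13L - 2L * u, N = 2L, O = 6L, P = 1L),
    HexCer = c(C = n + 6L, H = 2L * n + 11L - 2L * u, N = 1L, O = 8L, P = 0L)
  )
}

#' Monoisotopic mass and [M+H]+ m/z
#'
#' @param species A `lipid_species`.
#' @return Monoisotopic neutral mass in u (`monoisotopic_mass`) or the
#'   protonated m/z in Th (`precursor_mz_calc`).
#' @export
monoisotopic_mass <- function(species) {
  f <- molecular_formula(species)
  sum(f * .ELEMENT_MASS[names(f)])
}

#' @rdname monoisotopic_mass
#' @export
precursor_mz_calc <- function(species) {
  monoisotopic_mass(species) + .PROTON_MASS
}
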
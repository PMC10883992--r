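#' Configuration of the synthetic RT data generator
#'
#' The generator emulates the elution regularities of reversed-phase
#' sphingolipid LC-MS/MS: retention grows with fatty-acyl chain length,
#' shrinks with every C=C bond, SM elutes slightly earlier than Cer of equal
#' structure, gradient elution spaces species approximately linearly while
#' isocratic elution spreads them log-linearly (spacing widens with chain
#' length). Defaults are idealizations read off the bundled reference
#' tables' ranges (gradient Cer roughly 14-18 min, isocratic roughly
#' 3-13 min), not fits to them.
#'
#' @param mode `"gradient"` or `"isocratic"`.
#' @param variants Structural variants in the species grid, as
#'   `(base_unsat, acyl_unsat)` labels; default the five canonical ones.
#' @param chain_lengths Fatty-acyl carbon counts per variant.
#' @param classes Lipid classes to generate.
#' @param base_rt Gradient intercept (min) at zero carbons; default 8.9.
#' @param carbon_slope Gradient slope, min per acyl carbon (default 0.38).
#' @param unsat_penalty Gradient penalty, min per total C=C (default 0.25).
#' @param class_offset Additive shift for SM relative to Cer (min, default
#'   -0.35: SM elutes earlier at equal structure).
#' @param iso_base_rt Isocratic RT (min) of a C16, fully saturated Cer
#'   (default 3.5).
#' @param curvature Isocratic log-linear growth per acyl carbon (default
#'   0.165).
#' @param iso_unsat_penalty Isocratic log-scale penalty per C=C (default
#'   0.08).
#' @param iso_class_offset Isocratic log-scale SM shift (default -0.08).
#' @param noise_sd Gaussian RT noise, minutes (default 0.02).
#' @param n_studies Number of studies for [generate_rt_database()].
#' @param seed Integer seed.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(mode = c("gradient", "isocratic"),
                             variants = list(c(0L, 0L), c(1L, 0L), c(1L, 1L),
                                             c(2L, 0L), c(2L, 1L)),
                             chain_lengths = c(16L, 17L, 18L, 20L, 22L, 24L),
                             classes = "Cer",
                             base_rt = 8.9, carbon_slope = 0.38,
                             unsat_penalty = 0.25, class_offset = -0.35,
                             iso_base_rt = 3.5, curvature = 0.165,
                             iso_unsat_penalty = 0.08,
                             iso_class_offset = -0.08,
                             noise_sd = 0.02, n_studies = 12L, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(noise_sd >= 0, carbon_slope > 0, unsat_penalty > 0,
            length(chain_lengths) >= 1L, length(variants) >= 1L)
  structure(
    list(mode = mode, variants = variants, chain_lengths = chain_lengths,
         classes = classes, base_rt = base_rt, carbon_slope = carbon_slope,
         unsat_penalty = unsat_penalty, class_offset = class_offset,
         iso_base_rt = iso_base_rt, curvature = curvature,
         iso_unsat_penalty = iso_unsat_penalty,
         iso_class_offset = iso_class_offset,
         noise_sd = noise_sd, n_studies = as.integer(n_studies),
         seed = as.integer(seed)),
    class = "generator_config"
  )
}

.true_rt <- function(config, lipid_class, acyl_carbons, total_unsat) {
  if (config$mode == "gradient") {
    config$base_rt + config$carbon_slope * acyl_carbons -
      config$unsat_penalty * total_unsat +
      ifelse(lipid_class == "SM", config$class_offset, 0)
  } else {
    config$iso_base_rt * exp(
      config$curvature * (acyl_carbons - 16) -
        config$iso_unsat_penalty * total_unsat +
        ifelse(lipid_class == "SM", config$iso_class_offset, 0)
    )
  }
}

#' Generate one synthetic experiment with true RTs
#'
#' Builds the species grid (classes x structural variants x chain lengths,
#' with a d18:X backbone of 18 carbons), computes noiseless RTs from the
#' elution law of the configured mode, adds Gaussian noise, and returns an
#' experiment-table-shaped tibble in which every row carries its RT both as
#' `rt_user` (truth) and `rt_known` left blank until roles are chosen.
#'
#' @param config A [generator_config()].
#' @param train_names Optional character vector of lipid names to mark as
#'   Train (their `rt_known` is filled from the generated RT); all other
#'   rows are Test.
#' @return An [experiment_table()] with columns `rt_user` (generated RT) and
#'   `rt_true` (noiseless RT).
#' @export
generate_experiment <- function(config, train_names = character()) {
  stopifnot(inherits(config, "generator_config"))
  grid <- expand.grid(
    lipid_class = config$classes,
    variant = seq_along(config$variants),
    acyl_carbons = config$chain_lengths,
    stringsAsFactors = FALSE
  )
  if (!nrow(grid)) stop("empty species grid", call. = FALSE)
  base_unsat <- vapply(config$variants, `[`, integer(1), 1L)[grid$variant]
  acyl_unsat <- vapply(config$variants, `[`, integer(1), 2L)[grid$variant]
  species <- lapply(seq_len(nrow(grid)), function(i) {
    lipid_species(grid$lipid_class[i], "d", 18L, base_unsat[i],
                  grid$acyl_carbons[i], acyl_unsat[i])
  })
  mz <- vapply(species, precursor_mz_calc, numeric(1))
  rt_true <- .true_rt(config, grid$lipid_class, grid$acyl_carbons,
                      base_unsat + acyl_unsat)
  noise <- .with_seed(config$seed,
                      stats::rnorm(nrow(grid), 0, config$noise_sd))
  rt <- rt_true + noise
  tbl <- tibble::tibble(
    lipid_name = vapply(species, compose_lipid_name, character(1)),
    lipid_class = grid$lipid_class,
    backbone_hydroxyls = "d",
    base_carbons = 18L,
    base_unsat = base_unsat,
    acyl_carbons = grid$acyl_carbons,
    acyl_unsat = acyl_unsat,
    precursor_mz = round(mz, 1),
    role = ifelse(vapply(species, compose_lipid_name, character(1)) %in%
                    train_names, "train", "test"),
    rt_user = rt,
    rt_true = rt_true
  )
  tbl$rt_known <- ifelse(tbl$role == "train", tbl$rt_user, NA_real_)
  experiment_table(tbl, mode = config$mode)
}

#' Generate a multi-study RT database
#'
#' Each study draws its own intercept and carbon slope from Gaussian priors
#' around the configured values (defaults sd 0.10 min and 0.005 min/carbon,
#' a residual budget of about 0.15 min total cross-study dispersion against
#' the 0.25 min RMSE acceptance threshold), emulating
#' cross-laboratory variability between nominally similar separations, and
#' reports a random subset of the species grid (literature studies each
#' measure a partial panel, which is what makes small training collections
#' generalize poorly and the learning curve informative). Feeds
#' [run_learning_curve()].
#'
#' @param config A [generator_config()]; `n_studies >= 2`.
#' @param sd_base,sd_slope Cross-study prior standard deviations.
#' @param species_per_study Number of species each study reports (default 6;
#'   `Inf` keeps the full grid).
#' @return Tibble: the row-bound studies with a `study` column and `rt`.
#' @export
generate_rt_database <- function(config, sd_base = 0.10, sd_slope = 0.005,
                                 species_per_study = 6L) {
  stopifnot(inherits(config, "generator_config"))
  if (config$n_studies < 2L) {
    stop("n_studies must be at least 2", call. = FALSE)
  }
  draws <- .with_seed(config$seed, list(
    base = stats::rnorm(config$n_studies, config$base_rt, sd_base),
    slope = stats::rnorm(config$n_studies, config$carbon_slope, sd_slope),
    iso_base = stats::rnorm(config$n_studies, config$iso_base_rt,
                            sd_base),
    curv = stats::rnorm(config$n_studies, config$curvature, sd_slope)
  ))
  studies <- lapply(seq_len(config$n_studies), function(i) {
    cfg_i <- config
    cfg_i$base_rt <- draws$base[i]
    cfg_i$carbon_slope <- max(draws$slope[i], 1e-3)
    cfg_i$iso_base_rt <- max(draws$iso_base[i], 0.5)
    cfg_i$curvature <- max(draws$curv[i], 1e-3)
    cfg_i$seed <- config$seed + i
    tbl <- generate_experiment(cfg_i)
    tbl <- tibble::as_tibble(tbl)
    if (is.finite(species_per_study) && species_per_study < nrow(tbl)) {
      keep <- .with_seed(config$seed + 1000L + i,
                         sample(nrow(tbl), species_per_study))
      tbl <- tbl[sort(keep), , drop = FALSE]
    }
    tbl$study <- i
    tbl$rt <- tbl$rt_user
    tbl
  })
  dplyr::bind_rows(studies)
}
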
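test_that("isotope patterns follow the binomial 13C model", {
  p0 <- isotope_pattern(0)
  expect_equal(p0$abundances, c(1, 0, 0))
  # 41 * 0.0107 / 0.9893 = 0.443446 (binomial oracle)
  expect_equal(isotope_pattern(41)$abundances[2], 41 * 0.0107 / 0.9893,
               tolerance = 1e-12)
  expect_equal(round(isotope_pattern(41)$abundances[2], 3), 0.443)
  # M+1 abundance strictly increasing in carbon count
  m1 <- vapply(0:60, function(n) isotope_pattern(n)$abundances[2], numeric(1))
  expect_true(all(diff(m1) > 0))
  expect_error(isotope_pattern(-1), "non-negative")
})

test_that("isotope patterns agree with the exhaustive binomial oracle", {
  p <- 0.0107
  for (n in c(0:5, 17, 34, 41, 60)) {
    oracle <- dbinom(0:2, n, p) / dbinom(0, n, p)
    expect_equal(isotope_pattern(n)$abundances, oracle, tolerance = 1e-12)
  }
})

test_that("isobar enumeration matches the documented transitions", {
  cand <- suppressWarnings(
    enumerate_isobar_candidates(729.6, 184.1, class_hint = "SM"))
  expect_setequal(cand$lipid_name, c("SM (d18:1/18:1)", "SM (d18:2/18:0)"))
  expect_warning(enumerate_isobar_candidates(729.6, 184.1, class_hint = "SM"),
                 "phosphatidylcholine")
  backbone <- enumerate_isobar_candidates(729.6, 264.3, class_hint = "SM")
  expect_identical(backbone$lipid_name, "SM (d18:1/18:1)")
  for (mz in c(785.7, 813.7)) {
    cand <- suppressWarnings(
      enumerate_isobar_candidates(mz, 184.1, class_hint = "SM"))
    expect_identical(nrow(cand), 2L)
    expect_setequal(unique(cand$base_unsat + cand$acyl_unsat), 2L)
  }
  none <- suppressWarnings(enumerate_isobar_candidates(999.9, 184.1))
  expect_identical(nrow(none), 0L)
  # ranking by MRET plausibility against an observed peak
  preds <- tibble::tibble(lipid_name = c("SM (d18:1/18:1)", "SM (d18:2/18:0)"),
                          rt_predicted = c(14.72, 15.04))
  ranked <- suppressWarnings(enumerate_isobar_candidates(
    729.6, 184.1, class_hint = "SM", rt_predictions = preds,
    rt_observed = 15.0))
  expect_identical(ranked$lipid_name[1], "SM (d18:2/18:0)")
})

test_that("[M+1] interference needs both the mass and the RT to align", {
  hex <- parse_lipid_name("HexCer (d18:1/24:0)")
  target <- parse_lipid_name("SM (d18:1/24:1)")
  target$precursor_mz <- 813.7
  close_rt <- tibble::tibble(
    lipid_name = c("SM (d18:1/24:1)", "HexCer (d18:1/24:0)"),
    rt_predicted = c(9.89, 9.95))
  flagged <- flag_isotopologue_interference(target, list(hex), close_rt)
  expect_identical(flagged$lipid_name, "HexCer (d18:1/24:0)")
  expect_lt(abs(flagged$m1_mz - 813.7), 0.5)
  far_rt <- close_rt
  far_rt$rt_predicted[2] <- 12.95  # 3 min away: RT gate closes
  expect_identical(
    nrow(flag_isotopologue_interference(target, list(hex), far_rt)), 0L)
  expect_identical(
    nrow(flag_isotopologue_interference(target, list(), close_rt)), 0L)
})

test_that("peak assignment filters S/N, picks nearest RT, ignores list order", {
  peaks <- tibble::tibble(rt = c(14.5, 16.9), intensity = c(5, 3),
                          snr = c(10, 8))
  expect_equal(assign_peak(16.89, peaks, rt_tolerance = 0.2)$rt, 16.9)
  expect_null(assign_peak(10, peaks, rt_tolerance = 0.2))
  # sub-threshold peak at the predicted RT loses to a clean peak farther out
  noisy <- tibble::tibble(rt = c(16.89, 16.99), intensity = c(100, 10),
                          snr = c(2.5, 10))
  expect_equal(assign_peak(16.89, noisy, rt_tolerance = 0.2)$rt, 16.99)
  # order invariance and intensity tie-break, over random lists
  for (s in 1:20) {
    set.seed(s)
    pk <- tibble::tibble(rt = runif(6, 9, 11), intensity = runif(6, 1, 100),
                         snr = runif(6, 1, 12))
    a <- assign_peak(10, pk, rt_tolerance = 0.5)
    b <- assign_peak(10, pk[sample(6), ], rt_tolerance = 0.5)
    expect_identical(a, b)
    if (!is.null(a)) expect_gte(a$snr, 3)
  }
  tie <- tibble::tibble(rt = c(9.9, 10.1), intensity = c(1, 50),
                        snr = c(5, 5))
  expect_equal(assign_peak(10, tie, rt_tolerance = 0.5)$rt, 10.1)
})
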
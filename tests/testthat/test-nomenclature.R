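test_that("structure-level shorthand names parse to the right fields", {
  cases <- list(
    list("Cer (d18:1/17:0)", "Cer", "d", 18L, 1L, 17L, 0L),
    list("SM (d18:0/24:0)", "SM", "d", 18L, 0L, 24L, 0L),
    list("Cer(d18:1/24:0)", "Cer", "d", 18L, 1L, 24L, 0L),  # no space
    list("  HexCer ( d18:1 / 16:0 ) ", "HexCer", "d", 18L, 1L, 16L, 0L)
  )
  for (cs in cases) {
    sp <- parse_lipid_name(cs[[1]])
    expect_identical(sp$lipid_class, cs[[2]])
    expect_identical(sp$backbone_hydroxyls, cs[[3]])
    expect_identical(sp$base_carbons, cs[[4]])
    expect_identical(sp$base_unsat, cs[[5]])
    expect_identical(sp$acyl_carbons, cs[[6]])
    expect_identical(sp$acyl_unsat, cs[[7]])
  }
  expect_identical(parse_lipid_name("Cer(d18:1/24:0)"),
                   parse_lipid_name("Cer (d18:1/24:0)"))
})

test_that("malformed names fail with the offending token named", {
  expect_error(parse_lipid_name("Cer(18:1)"), "prefix")
  expect_error(parse_lipid_name("Foo (d18:1/16:0)"), "Foo")
  expect_error(parse_lipid_name("Cer (x18:1/16:0)"), "x")
  expect_error(parse_lipid_name("Cer d18:1/16:0"), "cannot parse")
  expect_error(lipid_species("Cer", "d", 30, 1, 16, 0), "base_carbons")
  expect_error(lipid_species("Cer", "d", 18, 3, 16, 0), "base_unsat")
})

test_that("sum compositions expand into the Fig-style isobar candidates", {
  sp <- parse_lipid_name("SM (d36:2)")
  expect_true(is.na(sp$base_carbons))
  cand <- vapply(attr(sp, "candidates"), compose_lipid_name, character(1))
  expect_setequal(cand, c("SM (d18:1/18:1)", "SM (d18:2/18:0)"))
  expect_identical(compose_lipid_name(sp), "SM (d36:2)")
})

test_that("parse . compose is the identity over a generated grammar", {
  grid <- expand.grid(cls = c("Cer", "SM", "HexCer"), b = c(16L, 18L, 20L),
                      u = 0:2, a = c(2L, 16L, 24L), v = 0:2,
                      stringsAsFactors = FALSE)
  for (i in seq_len(nrow(grid))) {
    name <- sprintf("%s (d%d:%d/%d:%d)", grid$cls[i], grid$b[i], grid$u[i],
                    grid$a[i], grid$v[i])
    expect_identical(compose_lipid_name(parse_lipid_name(name)), name)
  }
})

test_that("backbone fragments map to d18:X descriptors", {
  expect_identical(infer_backbone_from_fragments(264.3)$base_unsat, 1L)
  expect_identical(infer_backbone_from_fragments(262.3)$base_unsat, 2L)
  expect_identical(infer_backbone_from_fragments(266.3)$base_unsat, 0L)
  hg <- infer_backbone_from_fragments(184.0)
  expect_identical(hg$status, "undetermined")
  expect_identical(hg$headgroup, "SM")
  expect_error(infer_backbone_from_fragments(c(262.3, 264.3)),
               "conflicting")
})

test_that("fragment-deduced backbones agree with the names of the bundled tables", {
  tabs <- reference_rt_tables()
  for (w in tabs) {
    frag_col <- if ("product_mz2" %in% names(w)) w$product_mz2 else
      w$product_mz
    for (i in seq_len(nrow(w))) {
      sp <- parse_lipid_name(w$lipid_name[i])
      inferred <- infer_backbone_from_fragments(frag_col[i])
      expect_identical(inferred$base_unsat, sp$base_unsat,
                       info = w$lipid_name[i])
    }
  }
})

test_that("formula templates reproduce the printed precursor m/z within 0.5 Th", {
  tabs <- reference_rt_tables()
  for (w in tabs) {
    for (i in seq_len(nrow(w))) {
      sp <- parse_lipid_name(w$lipid_name[i])
      expect_lt(abs(precursor_mz_calc(sp) - w$precursor_mz[i]), 0.5,
                label = w$lipid_name[i])
    }
  }
})
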
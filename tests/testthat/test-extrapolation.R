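test_that("prediction requires two references and validates roles", {
  tab <- tibble::as_tibble(ref_exp("Cer", "serum"))
  tab$role <- "test"
  tab$rt_known <- NA_real_
  expect_error(predict_experiment(experiment_table(tab, "gradient")),
               "two Train references")
  tab$role[1] <- "train"
  expect_error(experiment_table(tab, "gradient"), "without a positive rt_known")
  tab$rt_known[1] <- tab$rt_user[1]
  expect_error(predict_experiment(experiment_table(tab, "gradient")),
               "got 1")
  bad <- tab
  bad$role[2] <- "reference"
  expect_error(experiment_table(bad, "gradient"), "invalid role token")
})

test_that("every row receives a prediction, in input order, references included", {
  tab <- ref_exp("Cer", "serum")
  pred <- predict_experiment(tab)
  expect_identical(pred$lipid_name, tab$lipid_name)
  expect_true(all(pred$rt_predicted > 0))
  expect_identical(nrow(pred), 26L)
  # train-only table: fitted values echoed for every row
  tr <- tibble::as_tibble(tab)[tab$role == "train", ]
  pt <- predict_experiment(experiment_table(tr, "gradient"))
  expect_identical(nrow(pt), sum(tab$role == "train"))
  expect_true(all(!is.na(pt$rt_predicted)))
})

test_that("permuting input rows permutes output identically", {
  tab <- ref_exp("SM", "csf")
  pred <- predict_experiment(tab)
  perm <- sample(nrow(tab))
  pred_perm <- predict_experiment(experiment_table(
    tibble::as_tibble(tab)[perm, ], "gradient"))
  expect_equal(pred_perm$rt_predicted, pred$rt_predicted[perm],
               tolerance = 1e-10)
})

test_that("reference fidelity: near-interpolation at train points", {
  tab <- ref_exp("Cer", "liver")
  pred <- predict_experiment(tab)
  model <- attr(pred, "model")
  tr <- pred[pred$role == "train", ]
  bound <- model$training_stats$rmse * sqrt(model$training_stats$n)
  expect_true(all(abs(tr$rt_predicted - tr$rt_known) <= bound + 1e-8))
  # with alpha -> 0 and a full-rank (square-ish) design: exact interpolation
  g <- tiny_gradient_table()
  rows <- tibble::as_tibble(g)[g$acyl_unsat == 0 & g$base_unsat == 1, ]
  rows$role <- "train"
  rows$rt_known <- rows$rt_user
  p <- predict_experiment(experiment_table(rows, "gradient"),
                          class_spec = regression_spec("ridge", 1e-10))
  expect_equal(p$rt_predicted, p$rt_known, tolerance = 1e-5)
})

test_that("elution order is recovered: RT grows with chain, falls with unsaturation", {
  check <- function(pred) {
    pred$variant <- sprintf("d18:%d/XX:%d", pred$base_unsat, pred$acyl_unsat)
    for (g in split(tibble::as_tibble(pred), pred$variant)) {
      g <- g[order(g$acyl_carbons), ]
      expect_true(all(diff(g$rt_predicted) > 0))
    }
    for (i in seq_len(nrow(pred))) for (j in seq_len(nrow(pred))) {
      if (pred$acyl_carbons[i] == pred$acyl_carbons[j] &&
          pred$base_unsat[j] + pred$acyl_unsat[j] ==
            pred$base_unsat[i] + pred$acyl_unsat[i] + 1L) {
        expect_lt(pred$rt_predicted[j], pred$rt_predicted[i])
      }
    }
  }
  # noiseless synthetic gradient data
  g <- tiny_gradient_table()
  refs <- g$lipid_name[g$acyl_carbons %in% c(16, 20, 24) |
                         g$lipid_name == "Cer (d18:1/17:0)"]
  gt <- tibble::as_tibble(g)
  gt$role <- ifelse(gt$lipid_name %in% refs, "train", "test")
  gt$rt_known <- ifelse(gt$role == "train", gt$rt_user, NA_real_)
  check(predict_experiment(experiment_table(gt, "gradient")))
  # bundled table predictions, gradient and isocratic
  for (cls in c("Cer", "SM")) for (e in c("serum", "brain")) {
    check(predict_experiment(ref_exp(cls, e)))
  }
})

test_that("small reference sets fall back to the restricted mass design", {
  tab <- tibble::as_tibble(ref_exp("Cer", "serum"))
  tab$role <- "test"
  tab$rt_known <- NA_real_
  idx <- c(4, 15, 26)  # three references spanning the mass range
  tab$role[idx] <- "train"
  tab$rt_known[idx] <- tab$rt_user[idx]
  pred <- predict_experiment(experiment_table(tab, "gradient"))
  model <- attr(pred, "model")
  expect_setequal(model$feature_names, c("mass", "mass_sq"))
  cmp <- !is.na(pred$rt_user)
  expect_lt(mean(percent_error(pred$rt_predicted[cmp], pred$rt_user[cmp])), 3)
})

test_that("mixed Cer/SM tables are refused, HexCer rides along", {
  cer <- tibble::as_tibble(ref_exp("Cer", "serum"))
  sm <- tibble::as_tibble(ref_exp("SM", "serum"))
  expect_error(predict_experiment(experiment_table(
    dplyr::bind_rows(cer, sm), "gradient")), "mixes lipid class")
  hex <- cer[1:2, ]
  hex$lipid_name <- c("HexCer (d18:1/16:0)", "HexCer (d18:1/24:0)")
  hex$lipid_class <- NULL
  hex <- hex[, c("lipid_name", "precursor_mz", "role", "rt_known", "rt_user")]
  hex$role <- "test"; hex$rt_known <- NA_real_
  mixed <- dplyr::bind_rows(
    cer[, c("lipid_name", "precursor_mz", "role", "rt_known", "rt_user")],
    hex)
  pred <- predict_experiment(experiment_table(mixed, "gradient"))
  expect_true(all(pred$rt_predicted > 0))
})

test_that("MRET profiles group by unsaturation variant with quadratic trendlines", {
  pred <- predict_experiment(ref_exp("SM", "serum"))
  prof <- build_mret_profile(pred)
  expect_identical(sort(unique(prof$points$group)),
                   c("d18:0/XX:0", "d18:1/XX:0", "d18:1/XX:1",
                     "d18:2/XX:0", "d18:2/XX:1"))
  expect_identical(nrow(prof$trendlines), 5L)
  expect_true(all(prof$trendlines$n_points >= 3))
  expect_true(all(!is.na(prof$trendlines$a)))
  # a 2-point group carries points but no trendline
  two <- tibble::tibble(
    lipid_name = c("Cer (d18:2/22:1)", "Cer (d18:2/24:1)"),
    lipid_class = "Cer", base_unsat = 2L, acyl_unsat = 1L,
    acyl_carbons = c(22L, 24L), precursor_mz = c(618.6, 646.6),
    rt_predicted = c(16.1, 16.8))
  p2 <- build_mret_profile(two)
  expect_identical(nrow(p2$points), 2L)
  expect_true(is.na(p2$trendlines$a))
  # collinear points: quadratic coefficient vanishes (least-squares oracle)
  lin <- tibble::tibble(
    lipid_name = letters[1:5], lipid_class = "Cer",
    base_unsat = 1L, acyl_unsat = 0L,
    precursor_mz = seq(500, 700, length.out = 5),
    rt_predicted = 2 + 0.01 * seq(500, 700, length.out = 5))
  pl <- build_mret_profile(lin)
  expect_equal(pl$trendlines$c, 0, tolerance = 1e-10)
  expect_equal(pl$trendlines$b, 0.01, tolerance = 1e-8)
})
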
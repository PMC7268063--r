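test_that("sorted round-robin partition deals subjects by trait rank", {
  fa <- sorted_partition(c(5, 1, 3, 2, 4), 2)
  # sorted values 1,2,3,4,5 alternate folds: {1,3,5} and {2,4}
  expect_setequal(c(5, 1, 3, 2, 4)[fa$fold_of == 1], c(1, 3, 5))
  expect_setequal(c(5, 1, 3, 2, 4)[fa$fold_of == 2], c(2, 4))

  fa2 <- sorted_partition(rnorm(20), 10)
  expect_true(all(table(fa2$fold_of) == 2))

  # tie-break: constant trait degrades to round-robin over input order
  fa3 <- sorted_partition(rep(1, 7), 3)
  expect_equal(fa3$fold_of, c(1L, 2L, 3L, 1L, 2L, 3L, 1L))

  # balance for arbitrary n, k
  set.seed(60)
  for (i in 1:20) {
    n <- sample(10:200, 1); k <- sample(2:10, 1)
    sz <- table(sorted_partition(rnorm(n), k)$fold_of)
    expect_lte(max(sz) - min(sz), 1)
    expect_length(sz, k)
  }
  expect_error(sorted_partition(rnorm(5), 1), "k")
})

test_that("evaluation metrics follow their definitional formulas", {
  y <- c(1, 3, 2, 5)
  ev <- evaluate_predictions(y, y)
  expect_equal(ev$R, 1); expect_equal(ev$MSE, 0)

  yc <- y - mean(y)
  expect_equal(evaluate_predictions(-yc, yc)$R, -1)

  pred <- c(1, 2, 3); actual <- c(2, 4, 9)
  ev2 <- evaluate_predictions(pred, actual)
  expect_equal(ev2$R, oracle_pearson(pred, actual), tolerance = 1e-12)
  expect_equal(ev2$MSE, mean(c(1, 2, 6)^2))

  evc <- evaluate_predictions(rep(2, 4), y)
  expect_equal(evc$R, 0)
  expect_true(evc$flagged)
  expect_error(evaluate_predictions(1:4, rep(1, 4)), "constant")
})

test_that("grid cardinalities match the protocol lists", {
  expect_equal(nrow(param_grid("without_replacement")), 180L)
  expect_equal(nrow(param_grid("with_replacement")), 36L)
  expect_equal(nrow(param_grid("without_replacement")) +
               nrow(param_grid("with_replacement")), 216L)
  # the 2 x 2 x 2 external-validation shortlist
  expect_length(validation_configs(), 8L)
})

test_that("run_cv recovers a strong noiseless signal almost perfectly", {
  # four positive planted edges at zero noise: per-edge rho = 0.5, so a
  # stringent screen isolates exactly the signal and both the univariate
  # CPM route and ridge interpolate it
  g <- generate_connectome(synthetic_spec(
    n_subjects = 300, n_nodes = 20, n_signal_edges = 4, noise_sd = 0,
    positive_fraction = 1, outlier_fraction = 0, hetero = FALSE, seed = 3))
  res <- run_cv(g$dataset, "score", selection = "baseline",
                models = c("cpm_p", "ridge"), alpha = 1e-6)
  expect_gt(res$cpm_p$mean_R, 0.99)
  expect_gt(res$ridge$mean_R, 0.99)
  expect_lt(res$ridge$mean_MSE, 1e-3)
})

test_that("run_cv is deterministic given the selection config", {
  g <- generate_connectome(synthetic_spec(
    n_subjects = 80, n_nodes = 15, n_signal_edges = 5, seed = 9))
  cfg <- bootstrap_config("without_replacement", nb = 20, bp = 0.7,
                          fp = 0.6, seed = 42)
  r1 <- run_cv(g$dataset, "score", selection = cfg, models = "ridge", k = 5)
  r2 <- run_cv(g$dataset, "score", selection = cfg, models = "ridge", k = 5)
  expect_identical(r1$per_fold_R, r2$per_fold_R)
  expect_identical(r1$per_fold_feature_count, r2$per_fold_feature_count)
  expect_identical(r1$hyperparams_chosen, r2$hyperparams_chosen)
})

test_that("feature selection and tuning never see the held-out fold", {
  # permuting the held-out fold's trait values (folds fixed) must leave
  # selected feature sets and chosen hyperparameters bit-identical
  g <- generate_connectome(synthetic_spec(
    n_subjects = 100, n_nodes = 15, n_signal_edges = 5, seed = 13))
  y <- g$dataset$traits$score
  X <- g$dataset$features
  folds <- sorted_partition(y, 5)
  cfg <- bootstrap_config("without_replacement", nb = 10, bp = 0.7,
                          fp = 0.5, seed = 5)
  for (sel in list("baseline", cfg)) {
    r1 <- run_cv(X, y, selection = sel, models = c("cpm_p", "lasso"),
                 k = 5, folds = folds)
    y2 <- y
    hold <- which(folds$fold_of == 2)
    y2[hold] <- y2[hold][c(length(hold):1)] # permute within fold 2
    r2 <- run_cv(X, y2, selection = sel, models = c("cpm_p", "lasso"),
                 k = 5, folds = folds)
    # fold 2's training subjects are untouched, so everything fitted for
    # fold 2 must be bit-identical (other folds see the permuted values in
    # their training data and may legitimately change)
    for (m in c("cpm_p", "lasso")) {
      expect_identical(r1[[m]]$per_fold_feature_count[2, ],
                       r2[[m]]$per_fold_feature_count[2, ])
      expect_identical(unclass(r1[[m]]$selected_sets[[2]]),
                       unclass(r2[[m]]$selected_sets[[2]]))
      expect_identical(r1[[m]]$hyperparams_chosen[[2]],
                       r2[[m]]$hyperparams_chosen[[2]])
    }
  }
})

test_that("run_cv on a pure-noise trait predicts near zero", {
  rs <- vapply(1:3, function(seed) {
    g <- generate_connectome(synthetic_spec(
      n_subjects = 120, n_nodes = 15, n_signal_edges = 0,
      outlier_fraction = 0, hetero = FALSE, seed = seed))
    run_cv(g$dataset, "score", selection = "baseline",
           models = "ridge", k = 5)$mean_R
  }, numeric(1))
  expect_true(all(abs(rs) < 0.35))
  expect_lt(abs(mean(rs)), 0.2)
})

test_that("grid_search shares folds, snapshots every NB and finds the best cell", {
  g <- generate_connectome(synthetic_spec(
    n_subjects = 90, n_nodes = 12, n_signal_edges = 4, seed = 17))
  gr <- grid_search(g$dataset, "score", models = "ridge",
                    scheme = "without_replacement",
                    nb_grid = c(5, 10), bp_grid = c(0.6, 0.8),
                    fp_grid = c(0.5, 0.8), k = 4, seed = 23)
  expect_equal(length(gr$results), 8L) # 2 x 2 x 2 cells
  expect_equal(nrow(gr$table), 8L)
  best_tab <- max(gr$table$mean_R)
  expect_equal(gr$best$ridge$result$mean_R, best_tab)

  # a single-config run reproduces the matching grid cell exactly
  cell <- gr$results[["without_replacement_nb10_bp0.8_fp0.5"]]$ridge
  cfg <- bootstrap_config("without_replacement", nb = 10, bp = 0.8,
                          fp = 0.5, seed = 23)
  solo <- run_cv(g$dataset, "score", selection = cfg, models = "ridge", k = 4)
  expect_equal(solo$per_fold_R, cell$per_fold_R, tolerance = 1e-12)
  expect_identical(solo$per_fold_feature_count, cell$per_fold_feature_count)

  # baseline rides along on the identical partition
  base <- run_cv(g$dataset, "score", selection = "baseline",
                 models = "ridge", k = 4)
  expect_equal(gr$baseline$ridge$per_fold_R, base$per_fold_R,
               tolerance = 1e-12)
})

test_that("grid ties break toward cheapest and most stringent config", {
  tab <- data.frame(config = c("a", "b", "c"), scheme = "without_replacement",
                    nb = c(100L, 10L, 10L), bp = c(0.5, 0.7, 0.5),
                    fp = c(0.8, 0.9, 0.9), model = "ridge",
                    mean_R = c(0.5, 0.5, 0.5))
  ord <- order(-tab$mean_R, tab$nb, -tab$fp, tab$bp)
  expect_equal(tab$config[ord[1]], "c") # smallest NB, largest FP, smallest BP
})

test_that("feature_dimension_report averages folds then traits", {
  mk <- function(counts) {
    structure(list(per_fold_feature_count =
                     matrix(counts, length(counts), 3,
                            dimnames = list(NULL, c("positive", "negative",
                                                    "combined")))),
              class = "prediction_result")
  }
  res <- list(traitA = list(baseline = mk(c(10, 20)), boot = mk(c(4, 6))),
              traitB = list(baseline = mk(c(10, 20)), boot = mk(c(2, 2))))
  rep <- feature_dimension_report(res)
  expect_equal(rep$per_trait["traitA", "baseline"], 15)
  expect_equal(rep$per_trait["traitA", "boot"], 5)
  expect_equal(rep$cross_trait_mean[["baseline"]], 15) # identical traits
  expect_equal(rep$cross_trait_mean[["boot"]], 3.5)
})

test_that("external validation transfers discovery models to held-out data", {
  spec <- synthetic_spec(n_subjects = 150, n_nodes = 15, n_signal_edges = 4,
                         noise_sd = 0, positive_fraction = 1,
                         outlier_fraction = 0, hetero = FALSE, seed = 31)
  tr <- generate_connectome(spec)
  # a copy of the training set as validation: noiseless signal transfers
  ev <- external_validate(tr$dataset, tr$dataset, "score",
                          configs = list("baseline"), models = "ridge",
                          alpha = 1e-6)
  expect_gt(ev$table$R[1], 0.99)

  # the default shortlist enumerates 8 bootstrap configs (+ baseline)
  ev2 <- external_validate(tr$dataset, tr$dataset, "score",
                           models = "cpm_p", alpha = 1e-6)
  expect_equal(sum(ev2$table$config != "baseline"), 8L)
  expect_equal(nrow(ev2$mean_over_configs), 1L)

  # dimension mismatch is caught
  small <- connectome_dataset(matrix(rnorm(50), 10, 5))
  expect_error(external_validate(tr$dataset, small,
                                 list(train = tr$dataset$traits$score,
                                      test = rnorm(10))), "mismatch")
})

test_that("independent validation cohorts track discovery performance", {
  spec_tr <- synthetic_spec(outlier_fraction = 0, hetero = FALSE, seed = 41)
  spec_te <- synthetic_spec(n_subjects = 150, outlier_fraction = 0,
                            hetero = FALSE, seed = 42)
  tr <- generate_connectome(spec_tr)
  te <- generate_connectome(spec_te)
  # same generative process, fresh subjects; signal edges differ across
  # specs, so plant the trait of the validation set with the training truth
  te_y <- withr::with_seed(43,
    as.vector(te$dataset$features[, tr$truth$signal_edges] %*%
                tr$truth$coefficients) + rnorm(150, sd = 0.12))
  cfg <- bootstrap_config("without_replacement", nb = 50, bp = 0.7,
                          fp = 0.7, seed = 41)
  cvres <- run_cv(tr$dataset, "score", selection = cfg, models = "ridge")
  withr::with_seed(42, {
    ev <- external_validate(tr$dataset, te$dataset,
                            list(train = tr$dataset$traits$score, test = te_y),
                            configs = list(cfg), models = "ridge")
  })
  expect_lt(abs(ev$table$R[1] - cvres$mean_R), 0.2)
  expect_gt(ev$table$R[1], 0.3) # genuine transfer, not chance
})
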
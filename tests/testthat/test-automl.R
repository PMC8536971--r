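# a small shared benchmark keeps the suite fast
benchSmall <- genQsarDataset(250, 12, 3, noiseSd = 0.4, seed = 21)

test_that("feature selection keeps everything at threshold 0 and scores top = 1", {
  fs <- selectFeatures(benchSmall$X, benchSmall$y, threshold = 0,
                       nTry = 2, seed = 1)
  expect_setequal(fs@names, colnames(benchSmall$X))
  expect_equal(max(fs@relativeImportance), 1)
  fs2 <- selectFeatures(benchSmall$X, benchSmall$y, threshold = 0.05,
                        nTry = 2, seed = 1)
  expect_true(all(fs2@relativeImportance >= 0.05))
  expect_true(length(fs2@names) >= 1L)
})

test_that("random search is seeded and budget-respecting", {
  folds <- kfoldSplit(nrow(benchSmall$X), 5, seed = 2)
  one <- randomSearch("gradient_boosting", benchSmall$X, benchSmall$y,
                      budget = 1, folds = folds, seed = 3)
  expect_length(one, 1L)
  again <- randomSearch("gradient_boosting", benchSmall$X, benchSmall$y,
                        budget = 1, folds = folds, seed = 3)
  expect_identical(one[[1]]$spec, again[[1]]$spec)
  expect_equal(one[[1]]$oof, again[[1]]$oof)
  # a larger budget with the same seed contains the budget-1 candidate, so
  # the best of 6 cannot be worse than the best of 1
  six <- randomSearch("gradient_boosting", benchSmall$X, benchSmall$y,
                      budget = 6, folds = folds, seed = 3)
  expect_identical(six[[1]]$spec, one[[1]]$spec)
  expect_lte(min(vapply(six, `[[`, numeric(1), "cvRmse")), one[[1]]$cvRmse)
})

test_that("a perfect base at lambda = 0 is reproduced exactly by the stack", {
  y <- benchSmall$y
  folds <- kfoldSplit(length(y), 5, seed = 1)
  cand <- mockCandidate("perfect", "linear_glm", oof = y)
  cand$cvRmse <- 0
  sm <- fitSuperLearner(list(cand), y, mode = "all", folds = folds,
                        lambda = 0)
  expect_equal(unname(sm@metalearner$weights), 1, tolerance = 1e-8)
  expect_equal(sm@metalearner$intercept, 0, tolerance = 1e-8)
  expect_equal(sm@cvMetrics$rmse, 0, tolerance = 1e-8)
})

test_that("the informative base outweighs a noise-corrupted copy", {
  set.seed(77)
  y <- benchSmall$y
  folds <- kfoldSplit(length(y), 5, seed = 1)
  noisy <- mockCandidate("noisy", "random_forest", oof = y + rnorm(length(y)))
  noisy$cvRmse <- rmse(y, noisy$oof)
  clean <- mockCandidate("clean", "gradient_boosting", oof = y)
  clean$cvRmse <- 0
  sm <- fitSuperLearner(list(noisy, clean), y, mode = "all", folds = folds)
  w <- sm@metalearner$weights
  expect_gt(w[["clean"]], w[["noisy"]])
  expect_true(all(w >= 0))
  expect_lte(sm@cvMetrics$rmse, noisy$cvRmse)
})

test_that("best-of-family keeps one candidate per family", {
  y <- benchSmall$y
  folds <- kfoldSplit(length(y), 5, seed = 1)
  set.seed(3)
  cands <- list(
    mockCandidate("gb1", "gradient_boosting", y + rnorm(length(y), 0, 0.8)),
    mockCandidate("gb2", "gradient_boosting", y + rnorm(length(y), 0, 0.2)),
    mockCandidate("rf1", "random_forest", y + rnorm(length(y), 0, 0.5)))
  for (i in seq_along(cands)) cands[[i]]$cvRmse <- rmse(y, cands[[i]]$oof)
  sm <- fitSuperLearner(cands, y, mode = "best_of_family", folds = folds)
  expect_setequal(names(sm@baseModels), c("gb2", "rf1"))
  expect_error(fitSuperLearner(list(), y, folds = folds), "at least one")
  short <- mockCandidate("bad", "random_forest", y[1:10])
  expect_error(fitSuperLearner(list(short), y, folds = folds),
               "fold assignment")
})

test_that("the full workflow is reproducible and its leaderboard complete", {
  res <- runAutoML(benchSmall$X, benchSmall$y, modelBudget = 2, nTry = 2,
                   k = 5, seed = 13,
                   families = c("gradient_boosting", "linear_glm",
                                "random_forest"))
  res2 <- runAutoML(benchSmall$X, benchSmall$y, modelBudget = 2, nTry = 2,
                    k = 5, seed = 13,
                    families = c("gradient_boosting", "linear_glm",
                                 "random_forest"))
  expect_identical(res$leaderboard, res2$leaderboard)
  lb <- res$leaderboard
  expect_equal(sum(lb$family != "stacked_ensemble"), 6L)  # 2 x 3 families
  expect_true(all(c("StackedEnsemble_All",
                    "StackedEnsemble_BestOfFamily") %in% lb$id))
  nb <- lb$n_bases[lb$id == "StackedEnsemble_BestOfFamily"]
  expect_lte(nb, length(learnerFamilies()))
  # winner is the lower-RMSE ensemble
  ensRows <- lb[lb$family == "stacked_ensemble", ]
  expect_equal(res$model@cvMetrics$rmse, min(ensRows$rmse))
  # metalearner non-negativity after every fit
  expect_true(all(res$ensembleAll@metalearner$weights >= 0))
  expect_true(all(res$ensembleBestOfFamily@metalearner$weights >= 0))
  # soft dominance: the stack is no worse than the best single candidate
  # plus a small slack
  bestSingle <- min(lb$rmse[lb$family != "stacked_ensemble"])
  expect_lte(res$ensembleAll@cvMetrics$rmse,
             bestSingle + 0.02 * sd(benchSmall$y))
  # prediction pathway works on new data
  p <- predict(res$model, benchSmall$X)
  expect_length(p, nrow(benchSmall$X))
})

test_that("fold-safe imputation handles missing descriptor cells", {
  X <- benchSmall$X
  set.seed(9)
  X[sample(length(X), 100)] <- NA
  res <- runAutoML(X, benchSmall$y, modelBudget = 1, nTry = 1, k = 5,
                   seed = 2, families = "gradient_boosting",
                   preprocessing = "fold_safe")
  expect_s4_class(res$model, "StackedModel")
})

test_that("the linear baseline behaves at both extremes", {
  set.seed(14)
  X <- matrix(rnorm(600), 200, 3, dimnames = list(NULL, c("a", "b", "c")))
  yLin <- drop(X %*% c(1, -2, 0.5)) + 7
  perfect <- fitLinearBaseline(X, yLin, k = 5, seed = 1)
  expect_lt(perfect$rmse, 1e-8)
  expect_gt(perfect$r2, 1 - 1e-8)
  yNull <- rnorm(200, 7)
  null <- fitLinearBaseline(X, yNull, k = 10, seed = 1)
  expect_lte(null$r2, 0.05)
  expect_length(null$fold_rmse, 10L)
})

test_that("OLS recovers known coefficients within three standard errors", {
  set.seed(23)
  X <- matrix(rnorm(1500), 500, 3, dimnames = list(NULL, c("a", "b", "c")))
  beta <- c(0.8, -1.2, 0.4)
  y <- drop(X %*% beta) + 7 + rnorm(500, 0, 0.5)
  sm <- summary(stats::lm(y ~ X))$coefficients
  expect_true(all(abs(sm[-1, "Estimate"] - beta) <= 3 * sm[-1, "Std. Error"]))
})
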
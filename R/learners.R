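# Base-learner families for the automated modeling workflow. The closed
# family list mirrors the algorithm classes of distributed tree ensembles
# and their relatives: random forest, extremely randomized trees, gradient
# boosting, extreme gradient boosting, regularized GLM, and a small fully
# connected neural network. Each family defines a hyperparameter space for
# random search plus fit/predict wrappers around the underlying engine
# (ranger, xgboost, glmnet, nnet) with single-threaded, seeded execution.

.learnerFamilies <- c("random_forest", "extremely_randomized_trees",
                      "gradient_boosting", "extreme_gradient_boosting",
                      "linear_glm", "neural_net")

#' List the available base-learner families
#'
#' @return character vector of family names.
#' @export
learnerFamilies <- function() .learnerFamilies

# uniform / log-uniform draws
.runifLog <- function(n, lo, hi) exp(stats::runif(n, log(lo), log(hi)))

# default hyperparameter spaces; scale-like parameters are drawn
# log-uniformly
.defaultSpace <- function(family) {
  switch(family,
    random_forest = list(
      num.trees = c(100L, 300L), mtry_frac = c(0.2, 0.9),
      min.node.size = c(1L, 10L)),
    extremely_randomized_trees = list(
      num.trees = c(100L, 300L), mtry_frac = c(0.2, 0.9),
      min.node.size = c(1L, 10L)),
    gradient_boosting = list(
      nrounds = c(50L, 300L), eta = c(0.03, 0.3), max_depth = c(2L, 7L),
      subsample = c(0.6, 1), colsample_bytree = c(0.5, 1)),
    extreme_gradient_boosting = list(
      nrounds = c(50L, 300L), eta = c(0.03, 0.3), max_depth = c(2L, 8L),
      subsample = c(0.6, 1), colsample_bytree = c(0.5, 1),
      lambda = c(0.1, 10), alpha = c(1e-3, 1), min_child_weight = c(1, 10)),
    linear_glm = list(alpha = c(0, 1), lambda = c(1e-4, 1)),
    neural_net = list(size = c(3L, 12L), decay = c(1e-4, 0.1),
                      maxit = c(100L, 250L)),
    stop("unknown learner family: ", family))
}

.sampleSpec <- function(family, space) {
  spec <- list()
  for (nm in names(space)) {
    rng <- space[[nm]]
    logScale <- nm %in% c("eta", "lambda", "alpha", "decay",
                          "min_child_weight") && all(rng > 0)
    val <- if (logScale) .runifLog(1, rng[1], rng[2]) else
      stats::runif(1, rng[1], rng[2])
    if (is.integer(rng)) val <- as.integer(round(val))
    spec[[nm]] <- val
  }
  spec
}

# fit one base learner on (X, y); X is a plain numeric matrix
.fitLearner <- function(family, X, y, spec, seed) {
  switch(family,
    random_forest = ,
    extremely_randomized_trees = {
      extra <- family == "extremely_randomized_trees"
      m <- ranger::ranger(
        x = as.data.frame(X), y = y,
        num.trees = spec$num.trees,
        mtry = max(1L, floor(spec$mtry_frac * ncol(X))),
        min.node.size = spec$min.node.size,
        splitrule = if (extra) "extratrees" else "variance",
        num.random.splits = 1L,
        seed = seed, num.threads = 1L)
      list(engine = "ranger", model = m)
    },
    gradient_boosting = ,
    extreme_gradient_boosting = {
      params <- list(objective = "reg:squarederror", eta = spec$eta,
                     max_depth = spec$max_depth, subsample = spec$subsample,
                     colsample_bytree = spec$colsample_bytree,
                     nthread = 1L, seed = seed)
      if (family == "extreme_gradient_boosting") {
        params$lambda <- spec$lambda
        params$alpha <- spec$alpha
        params$min_child_weight <- spec$min_child_weight
      } else {
        params$lambda <- 0   # classic gradient boosting: no shrinkage priors
        params$alpha <- 0
      }
      m <- xgboost::xgb.train(
        params = params,
        data = xgboost::xgb.DMatrix(X, label = y),
        nrounds = spec$nrounds, verbose = 0)
      list(engine = "xgboost", model = m)
    },
    linear_glm = {
      m <- glmnet::glmnet(X, y, alpha = spec$alpha, lambda = spec$lambda)
      list(engine = "glmnet", model = m, lambda = spec$lambda)
    },
    neural_net = {
      mu <- colMeans(X); sdv <- apply(X, 2, stats::sd)
      sdv[sdv == 0] <- 1
      Xs <- scale(X, mu, sdv)
      m <- .withSeed(seed, nnet::nnet(
        x = Xs, y = y, size = spec$size, decay = spec$decay,
        maxit = spec$maxit, linout = TRUE, trace = FALSE,
        MaxNWts = 5000L))
      list(engine = "nnet", model = m, center = mu, scale = sdv)
    },
    stop("unknown learner family: ", family))
}

.predictLearner <- function(fit, X) {
  switch(fit$engine,
    ranger = predict(fit$model, as.data.frame(X),
                     num.threads = 1L)$predictions,
    xgboost = predict(fit$model, xgboost::xgb.DMatrix(X)),
    glmnet = as.numeric(predict(fit$model, X, s = fit$lambda)),
    nnet = as.numeric(predict(fit$model, scale(X, fit$center, fit$scale))),
    stop("unknown engine"))
}

# Fit a candidate across folds to obtain out-of-fold predictions, plus a
# full-data refit used for deployment-time prediction. When per-fold
# training matrices are supplied (fold-safe imputation), they are used for
# the fold fits.
.fitCandidate <- function(family, X, y, spec, folds, seed,
                          foldMatrices = NULL) {
  oof <- rep(NA_real_, length(y))
  for (f in sort(unique(folds))) {
    tr <- folds != f
    Xf <- if (is.null(foldMatrices)) X else foldMatrices[[f]]
    fit <- .fitLearner(family, Xf[tr, , drop = FALSE], y[tr], spec,
                       seed = deriveSeed(seed, paste0("fold", f)))
    oof[!tr] <- .predictLearner(fit, Xf[!tr, , drop = FALSE])
  }
  full <- .fitLearner(family, X, y, spec, seed = deriveSeed(seed, "full"))
  pred <- local({
    fitLocal <- full
    function(Xnew) .predictLearner(fitLocal, Xnew)
  })
  list(family = family, spec = spec, oof = oof, predict = pred,
       cvRmse = rmse(y, oof), cvR2 = rSquared(y, oof), seed = seed)
}

#' Random hyperparameter search for one learner family
#'
#' Samples \code{budget} hyperparameter configurations (uniformly;
#' log-uniformly for scale-like parameters) from the family's space, fits
#' each configuration per cross-validation fold to obtain out-of-fold
#' predictions, and returns the fitted candidates with their CV RMSE.
#'
#' @param family one of [learnerFamilies()].
#' @param X numeric feature matrix.
#' @param y numeric response.
#' @param budget number of configurations to draw (>= 1).
#' @param folds integer fold assignment from [kfoldSplit()].
#' @param seed integer seed; the sampled specs are a deterministic function
#'   of it.
#' @param space optional list of parameter ranges overriding the default
#'   space.
#' @param foldMatrices optional list of per-fold training matrices
#'   (fold-safe imputation).
#' @return list of candidate objects (family, spec, oof, predict, cvRmse).
#' @export
randomSearch <- function(family, X, y, budget, folds, seed = 1L,
                         space = NULL, foldMatrices = NULL) {
  family <- match.arg(family, .learnerFamilies)
  .assertScalarNumber(budget, "budget", 1)
  if (is.null(space)) space <- .defaultSpace(family)
  if (length(space) == 0L) stop("empty hyperparameter space")
  specs <- .withSeed(deriveSeed(seed, paste0("space/", family)), {
    lapply(seq_len(budget), function(i) .sampleSpec(family, space))
  })
  lapply(seq_along(specs), function(i) {
    cand <- .fitCandidate(family, X, y, specs[[i]], folds,
                          seed = deriveSeed(seed, paste0(family, "/", i)),
                          foldMatrices = foldMatrices)
    cand$id <- sprintf("%s_%d", family, i)
    cand
  })
}
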
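# The four-stage automated modeling workflow: importance-threshold feature
# selection, algorithm selection over the base-learner families, random
# hyperparameter search, and super-learner stacking with a non-negative
# L1/elastic-net linear metalearner, all evaluated by seeded 10-fold
# cross-validation.

#' Select features by averaged importance screening
#'
#' Fits \code{nTry} seeded gradient-boosting screening models, averages the
#' per-feature importance (gain) across tries, normalizes by the maximum so
#' the top feature scores exactly 1, and keeps features whose relative
#' importance is at least \code{threshold}. The top feature is always
#' retained.
#'
#' @param X numeric matrix (or \linkS4class{PreprocessedMatrix}).
#' @param y numeric response.
#' @param threshold relative-importance cutoff in [0, 1] (default 0.05).
#' @param nTry number of screening repetitions (default 5).
#' @param seed integer seed.
#' @param screenParams optional override of the screening model parameters.
#' @return a \linkS4class{FeatureSubset}.
#' @export
selectFeatures <- function(X, y, threshold = 0.05, nTry = 5L, seed = 1L,
                           screenParams = NULL) {
  X <- .asFeatureMatrix(X)
  if (ncol(X) == 0L || nrow(X) == 0L) stop("X must be nonempty")
  if (threshold < 0 || threshold > 1) stop("threshold must be in [0, 1]")
  .assertScalarNumber(nTry, "nTry", 1)
  params <- utils::modifyList(
    list(objective = "reg:squarederror", eta = 0.1, max_depth = 5,
         subsample = 0.8, colsample_bytree = 0.8, nthread = 1L),
    if (is.null(screenParams)) list() else screenParams)
  nrounds <- params$nrounds %||% 150L
  params$nrounds <- NULL

  total <- stats::setNames(numeric(ncol(X)), colnames(X))
  for (i in seq_len(nTry)) {
    p <- params
    p$seed <- deriveSeed(seed, paste0("screen", i))
    bst <- xgboost::xgb.train(params = p,
                              data = xgboost::xgb.DMatrix(X, label = y),
                              nrounds = nrounds, verbose = 0)
    imp <- xgboost::xgb.importance(model = bst)
    total[imp$Feature] <- total[imp$Feature] + imp$Gain
  }
  rel <- total / max(total)
  sel <- names(rel)[rel >= threshold]
  if (length(sel) == 0L) sel <- names(which.max(rel))
  sel <- sel[order(-rel[sel])]
  new("FeatureSubset", names = sel,
      relativeImportance = stats::setNames(unname(rel[sel]), sel),
      threshold = threshold, allImportance = sort(rel, decreasing = TRUE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.asFeatureMatrix <- function(X) {
  if (is(X, "DescriptorMatrix")) X <- descriptorValues(X)
  if (is.data.frame(X)) X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (is.null(colnames(X))) colnames(X) <- sprintf("V%d", seq_len(ncol(X)))
  X
}

# non-negative regularized linear metalearner on the out-of-fold prediction
# matrix; lambda chosen by inner cross-validation over a log-spaced grid
.fitMetalearner <- function(Z, y, penalty = c("lasso", "elastic"),
                            lambda = NULL, seed = 1L, nLambda = 20L) {
  penalty <- match.arg(penalty)
  alpha <- if (penalty == "lasso") 1 else 0.5
  if (ncol(Z) == 1L) {
    # degenerate single-base stack: unpenalized non-negative least squares
    z <- Z[, 1]
    b <- if (stats::var(z) > 0) {
      max(0, stats::cov(z, y) / stats::var(z))
    } else 0
    a <- mean(y) - b * mean(z)
    return(list(intercept = a,
                weights = stats::setNames(b, colnames(Z)),
                penalty = penalty, lambda = lambda %||% 0))
  }
  if (!is.null(lambda)) {
    fit <- glmnet::glmnet(Z, y, alpha = alpha, lower.limits = 0,
                          lambda = sort(c(lambda, lambda * 10,
                                          lambda * 100), decreasing = TRUE))
    co <- as.numeric(stats::coef(fit, s = lambda, exact = FALSE))
  } else {
    grid <- exp(seq(log(1e-5), log(1), length.out = nLambda)) * max(1, stats::sd(y))
    foldid <- .withSeed(deriveSeed(seed, "metalambda"),
                        sample(rep_len(1:5, length(y))))
    cvfit <- glmnet::cv.glmnet(Z, y, alpha = alpha, lower.limits = 0,
                               lambda = sort(grid, decreasing = TRUE),
                               foldid = foldid)
    lambda <- cvfit$lambda.min
    co <- as.numeric(stats::coef(cvfit, s = "lambda.min"))
  }
  list(intercept = co[1],
       weights = stats::setNames(pmax(co[-1], 0), colnames(Z)),
       penalty = penalty, lambda = lambda)
}

#' Fit a super learner over base candidates
#'
#' Builds the level-one matrix from the candidates' out-of-fold predictions
#' (all candidates must share one fold assignment) and fits a generalized
#' linear metalearner by coordinate descent under a non-negativity
#' constraint with Lasso or elastic-net regularization; lambda is chosen by
#' inner 5-fold cross-validation unless given. Mode "best_of_family" first
#' keeps only the lowest-RMSE candidate per family, so the stack contains at
#' most one base per family.
#'
#' @param candidates list of candidates from [randomSearch()] (or
#'   hand-built: list with \code{family}, \code{oof}, \code{predict},
#'   \code{cvRmse}, \code{id}).
#' @param y numeric response the candidates were trained on.
#' @param mode "all" (default) or "best_of_family".
#' @param folds integer fold assignment shared by all candidates.
#' @param penalty "lasso" (default) or "elastic" (mixing 0.5).
#' @param lambda optional fixed penalty (e.g. 0 for the unregularized
#'   exact-fit limit); chosen by inner CV when NULL.
#' @param seed integer seed for the inner CV.
#' @return a \linkS4class{StackedModel}.
#' @export
fitSuperLearner <- function(candidates, y, mode = c("all", "best_of_family"),
                            folds, penalty = c("lasso", "elastic"),
                            lambda = NULL, seed = 1L) {
  mode <- match.arg(mode)
  penalty <- match.arg(penalty)
  if (length(candidates) < 1L) stop("need at least one base candidate")
  for (cand in candidates) {
    if (length(cand$oof) != length(y)) {
      stop("candidate '", cand$id %||% cand$family,
           "' has out-of-fold predictions of the wrong length ",
           "(fold assignment mismatch)")
    }
  }
  if (mode == "best_of_family") {
    fams <- vapply(candidates, `[[`, character(1), "family")
    keep <- vapply(split(seq_along(candidates), fams), function(idx) {
      idx[which.min(vapply(candidates[idx], `[[`, numeric(1), "cvRmse"))]
    }, integer(1))
    candidates <- candidates[sort(keep)]
  }
  ids <- vapply(seq_along(candidates), function(i) {
    candidates[[i]]$id %||% sprintf("base_%d", i)
  }, character(1))
  Z <- do.call(cbind, lapply(candidates, `[[`, "oof"))
  colnames(Z) <- ids
  meta <- .fitMetalearner(Z, y, penalty = penalty, lambda = lambda,
                          seed = seed)
  oofStack <- as.numeric(meta$intercept + Z %*% meta$weights)
  cv <- .cvMetricsFromOOF(y, oofStack, folds)
  new("StackedModel",
      baseModels = stats::setNames(candidates, ids),
      metalearner = meta,
      ensembleMode = mode,
      cvMetrics = cv,
      folds = as.integer(folds),
      featureNames = character(0))
}

#' Predict from a stacked model
#'
#' intercept + sum of w_j * base_j(x), every w_j >= 0.
#'
#' @param object a \linkS4class{StackedModel}.
#' @param newdata numeric matrix with the model's feature columns.
#' @return numeric predictions.
#' @export
setMethod("predict", "StackedModel", function(object, newdata) {
  X <- .asFeatureMatrix(newdata)
  if (length(object@featureNames)) {
    miss <- setdiff(object@featureNames, colnames(X))
    if (length(miss)) {
      stop("newdata is missing feature columns: ",
           paste(utils::head(miss, 5), collapse = ", "))
    }
    X <- X[, object@featureNames, drop = FALSE]
  }
  w <- object@metalearner$weights
  preds <- vapply(names(object@baseModels), function(id) {
    if (w[[id]] > 0) object@baseModels[[id]]$predict(X) else
      numeric(nrow(X))
  }, numeric(nrow(X)))
  if (is.null(dim(preds))) preds <- matrix(preds, nrow = nrow(X))
  as.numeric(object@metalearner$intercept + preds %*% w)
})

#' Cross-validated ordinary-least-squares baseline
#'
#' Fits OLS on the selected features and evaluates it on the same folds as
#' the ensembles. Rank-deficient designs fall back to a small ridge penalty
#' with a warning.
#'
#' @param X numeric matrix of (selected) features.
#' @param y numeric response.
#' @param folds fold assignment (default a fresh [kfoldSplit()]).
#' @param k folds when \code{folds} is NULL.
#' @param seed integer seed.
#' @return list of CV metrics (rmse, r2, n, per-fold values, oof).
#' @export
fitLinearBaseline <- function(X, y, folds = NULL, k = 10, seed = 1L) {
  X <- .asFeatureMatrix(X)
  if (is.null(folds)) folds <- kfoldSplit(length(y), k, seed)
  oof <- rep(NA_real_, length(y))
  ridged <- FALSE
  for (f in sort(unique(folds))) {
    tr <- folds != f
    Xtr <- cbind(1, X[tr, , drop = FALSE])
    fit <- tryCatch(stats::lm.fit(Xtr, y[tr]), error = function(e) NULL)
    if (is.null(fit) || any(is.na(fit$coefficients))) {
      ridged <- TRUE
      XtX <- crossprod(Xtr)
      lam <- 1e-8 * mean(diag(XtX))   # scale-aware ridge
      beta <- tryCatch(solve(XtX + diag(lam, ncol(Xtr)),
                             crossprod(Xtr, y[tr])),
                       error = function(e) {
                         solve(XtX + diag(1e-4 * mean(diag(XtX)),
                                          ncol(Xtr)),
                               crossprod(Xtr, y[tr]))
                       })
    } else {
      beta <- fit$coefficients
    }
    oof[!tr] <- cbind(1, X[!tr, , drop = FALSE]) %*% beta
  }
  if (ridged) {
    warning("rank-deficient design; ridge fallback used", call. = FALSE)
  }
  .cvMetricsFromOOF(y, oof, folds)
}

# fold-safe preprocessing: per-fold matrices whose imputation means come
# from the training folds only
.foldImputedMatrices <- function(values, folds) {
  lapply(sort(unique(folds)), function(f) {
    tr <- folds != f
    mu <- colMeans(values[tr, , drop = FALSE], na.rm = TRUE)
    mu[!is.finite(mu)] <- 0
    out <- values
    for (j in seq_len(ncol(out))) {
      idx <- is.na(out[, j])
      if (any(idx)) out[idx, j] <- mu[j]
    }
    out
  })
}

#' Run the full automated modeling workflow
#'
#' Executes the four stages in order: (1) feature selection by averaged
#' importance screening, (2) algorithm selection over the configured
#' base-learner families, (3) random hyperparameter search within each
#' family, and (4) super-learner stacking, building both the "all" ensemble
#' (every fitted candidate) and the "best of family" ensemble (at most one
#' base per family, the production configuration). The returned model is
#' the lower-RMSE ensemble; ties break toward fewer base models, then
#' lexical id. Fully reproducible from \code{seed}.
#'
#' @param X numeric matrix, \linkS4class{DescriptorMatrix} or
#'   \linkS4class{PreprocessedMatrix}.
#' @param y numeric response aligned with X.
#' @param modelBudget candidates per family (default 10).
#' @param nTry screening repetitions for feature selection (default 5).
#' @param threshold feature-selection relative-importance cutoff
#'   (default 0.05).
#' @param k cross-validation folds (default 10).
#' @param seed global integer seed.
#' @param families subset of [learnerFamilies()] to search (default all;
#'   the neural-net family can be dropped for speed).
#' @param penalty metalearner penalty ("lasso" default, or "elastic").
#' @param preprocessing "fold_safe" (default; imputation means from
#'   training folds) or "global" (means from the full matrix).
#' @param selectFirst run the feature-selection stage (default TRUE).
#' @return list with \code{model} (the winning \linkS4class{StackedModel}),
#'   \code{ensembleAll}, \code{ensembleBestOfFamily}, \code{features}
#'   (\linkS4class{FeatureSubset}), \code{leaderboard} (data.frame),
#'   \code{folds}, \code{baseline} (OLS CV metrics).
#' @export
runAutoML <- function(X, y, modelBudget = 10L, nTry = 5L, threshold = 0.05,
                      k = 10L, seed = 1L,
                      families = learnerFamilies(),
                      penalty = c("lasso", "elastic"),
                      preprocessing = c("fold_safe", "global"),
                      selectFirst = TRUE) {
  penalty <- match.arg(penalty)
  preprocessing <- match.arg(preprocessing)
  families <- match.arg(families, .learnerFamilies, several.ok = TRUE)
  .assertScalarNumber(modelBudget, "modelBudget", 1)
  Xfull <- .asFeatureMatrix(X)
  if (nrow(Xfull) != length(y)) stop("X and y are not aligned")
  folds <- kfoldSplit(length(y), k, seed = deriveSeed(seed, "folds"))

  hasNA <- anyNA(Xfull)
  Xsel <- Xfull
  if (hasNA) {
    mu <- colMeans(Xfull, na.rm = TRUE); mu[!is.finite(mu)] <- 0
    for (j in seq_len(ncol(Xsel))) {
      idx <- is.na(Xsel[, j]); if (any(idx)) Xsel[idx, j] <- mu[j]
    }
  }

  features <- if (selectFirst) {
    selectFeatures(Xsel, y, threshold = threshold, nTry = nTry,
                   seed = deriveSeed(seed, "select"))
  } else {
    new("FeatureSubset", names = colnames(Xsel),
        relativeImportance = stats::setNames(rep(1, ncol(Xsel)),
                                             colnames(Xsel)),
        threshold = 0,
        allImportance = stats::setNames(rep(1, ncol(Xsel)), colnames(Xsel)))
  }
  sel <- features@names
  Xs <- Xsel[, sel, drop = FALSE]
  foldMatrices <- NULL
  if (hasNA && preprocessing == "fold_safe") {
    foldMatrices <- .foldImputedMatrices(Xfull[, sel, drop = FALSE], folds)
  }

  candidates <- list()
  for (fam in families) {
    candidates <- c(candidates, randomSearch(
      fam, Xs, y, budget = modelBudget, folds = folds,
      seed = deriveSeed(seed, paste0("search/", fam)),
      foldMatrices = foldMatrices))
  }

  ensAll <- fitSuperLearner(candidates, y, mode = "all", folds = folds,
                            penalty = penalty,
                            seed = deriveSeed(seed, "meta/all"))
  ensBof <- fitSuperLearner(candidates, y, mode = "best_of_family",
                            folds = folds, penalty = penalty,
                            seed = deriveSeed(seed, "meta/bof"))
  ensAll@featureNames <- sel
  ensBof@featureNames <- sel

  lb <- rbind(
    data.frame(id = vapply(candidates, `[[`, character(1), "id"),
               family = vapply(candidates, `[[`, character(1), "family"),
               n_bases = 1L,
               rmse = vapply(candidates, `[[`, numeric(1), "cvRmse"),
               r2 = vapply(candidates, `[[`, numeric(1), "cvR2"),
               stringsAsFactors = FALSE),
    data.frame(id = c("StackedEnsemble_All", "StackedEnsemble_BestOfFamily"),
               family = "stacked_ensemble",
               n_bases = c(length(ensAll@baseModels),
                           length(ensBof@baseModels)),
               rmse = c(ensAll@cvMetrics$rmse, ensBof@cvMetrics$rmse),
               r2 = c(ensAll@cvMetrics$r2, ensBof@cvMetrics$r2),
               stringsAsFactors = FALSE))
  lb <- lb[order(lb$rmse, lb$n_bases, lb$id), ]
  rownames(lb) <- NULL

  pick <- order(c(ensAll@cvMetrics$rmse, ensBof@cvMetrics$rmse),
                c(length(ensAll@baseModels), length(ensBof@baseModels)),
                c("StackedEnsemble_All", "StackedEnsemble_BestOfFamily"))[1]
  model <- if (pick == 1L) ensAll else ensBof

  baseline <- suppressWarnings(
    fitLinearBaseline(Xs, y, folds = folds))

  list(model = model, ensembleAll = ensAll, ensembleBestOfFamily = ensBof,
       features = features, leaderboard = lb, folds = folds,
       baseline = baseline, seed = seed)
}
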
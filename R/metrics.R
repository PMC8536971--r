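# Goodness-of-fit metrics and cross-validation folds.

#' Root-mean-square error
#'
#' sqrt(mean((pred - obs)^2)), in the units of the response.
#'
#' @param obs,pred numeric vectors of equal length.
#' @return non-negative scalar.
#' @examples
#' rmse(c(6, 7, 8), c(6.5, 7, 7.5))  # sqrt(1/6)
#' @export
rmse <- function(obs, pred) {
  if (length(obs) != length(pred)) {
    stop("obs and pred must have the same length")
  }
  if (length(obs) == 0L) stop("empty input")
  sqrt(mean((pred - obs)^2))
}

#' Coefficient of determination
#'
#' 1 - SS_res / SS_tot, with SS_tot taken about the observed mean. Can be
#' negative for predictions worse than the mean.
#'
#' @param obs,pred numeric vectors of equal length (>= 2).
#' @return scalar <= 1.
#' @examples
#' rSquared(c(6, 7, 8), c(6.5, 7, 7.5))  # 0.75
#' @export
rSquared <- function(obs, pred) {
  if (length(obs) != length(pred)) {
    stop("obs and pred must have the same length")
  }
  if (length(obs) < 2L) stop("need at least two observations")
  ssTot <- sum((obs - mean(obs))^2)
  if (ssTot == 0) stop("R-squared is undefined for constant observations")
  1 - sum((pred - obs)^2) / ssTot
}

#' Balanced k-fold assignment
#'
#' Random, seeded partition of n records into k folds whose sizes differ by
#' at most one.
#'
#' @param n number of records.
#' @param k number of folds (default 10).
#' @param seed integer seed.
#' @return integer vector of fold labels in 1..k.
#' @examples
#' table(kfoldSplit(23, 10, seed = 1))  # sizes 3,3,3,2,2,2,2,2,2,2
#' @export
kfoldSplit <- function(n, k = 10, seed = 1L) {
  .assertScalarNumber(n, "n", 1); .assertScalarNumber(k, "k", 2)
  if (n < k) stop("n must be at least k")
  .withSeed(deriveSeed(seed, "kfold"), {
    sample(rep_len(seq_len(k), n))
  })
}

# pooled + per-fold metrics from out-of-fold predictions
.cvMetricsFromOOF <- function(obs, oof, folds) {
  perFold <- vapply(sort(unique(folds)), function(f) {
    idx <- folds == f
    c(rmse(obs[idx], oof[idx]),
      if (sum(idx) >= 2 && stats::sd(obs[idx]) > 0)
        rSquared(obs[idx], oof[idx]) else NA_real_)
  }, numeric(2))
  list(rmse = rmse(obs, oof), r2 = rSquared(obs, oof), n = length(obs),
       fold_rmse = perFold[1, ], fold_r2 = perFold[2, ], oof = oof)
}
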
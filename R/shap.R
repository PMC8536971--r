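# Shapley-value attribution for fitted predictors: exact enumeration over
# all feature coalitions for small feature counts, and a seeded
# permutation-sampling estimator otherwise. Absent features are marginalized
# by replacement with background-sample values (interventional/marginal
# expectation), so for the exact method on a deterministic model the
# attributions satisfy local accuracy: phi0 + sum_j phi_ij = f(x_i).

.predFun <- function(model) {
  if (is.function(model)) return(function(X) as.numeric(model(X)))
  if (is(model, "StackedModel")) return(function(X) predict(model, X))
  if (!is.null(attr(model, "predict"))) return(attr(model, "predict"))
  stop("model must be a function(X) -> numeric or a StackedModel")
}

.shapExact <- function(f, Xb, Xe) {
  p <- ncol(Xe)
  nE <- nrow(Xe); nB <- nrow(Xb)
  if (p > 12L) {
    stop("exact Shapley enumeration is limited to 12 features (",
         p, " given); use method = 'sampling'")
  }
  subsets <- lapply(0:(2^p - 1L), function(m) which(bitwAnd(m, 2^(0:(p - 1))) > 0))
  lfact <- lgamma(seq_len(p + 1))  # lfact[k+1] = log(k!)
  phi <- matrix(0, nE, p, dimnames = list(NULL, colnames(Xe)))
  vAll <- matrix(NA_real_, nE, length(subsets))
  for (s in seq_along(subsets)) {
    S <- subsets[[s]]
    # value of coalition S for every explained record: average model output
    # with features in S from x and the rest from each background row
    big <- Xb[rep(seq_len(nB), times = nE), , drop = FALSE]
    if (length(S)) {
      for (j in S) big[, j] <- rep(Xe[, j], each = nB)
    }
    pr <- f(big)
    vAll[, s] <- colMeans(matrix(pr, nB, nE))
  }
  key <- vapply(subsets, function(S) sum(2^(S - 1)), numeric(1))
  lookup <- match(0:(2^p - 1L), key)
  for (j in seq_len(p)) {
    bit <- 2^(j - 1)
    for (s in seq_along(subsets)) {
      m <- key[s]
      if (bitwAnd(m, bit) > 0) next
      sz <- length(subsets[[s]])
      w <- exp(lfact[sz + 1] + lfact[p - sz] - lfact[p + 1])
      withJ <- lookup[m + bit + 1L]
      phi[, j] <- phi[, j] + w * (vAll[, withJ] - vAll[, s])
    }
  }
  list(phi = phi, base = mean(f(Xb)))
}

.shapSampling <- function(f, Xb, Xe, nSamples, seed) {
  p <- ncol(Xe); nE <- nrow(Xe); nB <- nrow(Xb)
  phi <- matrix(0, nE, p, dimnames = list(NULL, colnames(Xe)))
  .withSeed(deriveSeed(seed, "shap-sampling"), {
    perms <- replicate(nSamples, sample.int(p), simplify = FALSE)
    bIdx <- sample.int(nB, nSamples, replace = TRUE)
    for (i in seq_len(nE)) {
      x <- Xe[i, ]
      # one permutation walk per draw: start from the background row, add
      # features in permutation order, record marginal contributions
      contrib <- matrix(0, nSamples, p)
      steps <- matrix(NA_real_, nSamples * (p + 1), p)
      colnames(steps) <- colnames(Xe)
      for (d in seq_len(nSamples)) {
        cur <- Xb[bIdx[d], ]
        row0 <- (d - 1L) * (p + 1L)
        steps[row0 + 1L, ] <- cur
        for (t in seq_len(p)) {
          cur[perms[[d]][t]] <- x[perms[[d]][t]]
          steps[row0 + t + 1L, ] <- cur
        }
      }
      pr <- f(steps)
      for (d in seq_len(nSamples)) {
        row0 <- (d - 1L) * (p + 1L)
        diffs <- pr[row0 + 1L + seq_len(p)] - pr[row0 + seq_len(p)]
        contrib[d, perms[[d]]] <- diffs
      }
      phi[i, ] <- colMeans(contrib)
    }
  })
  list(phi = phi, base = mean(f(Xb)))
}

#' Shapley attributions for a fitted model
#'
#' Computes per-record, per-feature attributions phi (in units of the model
#' response) with respect to a background sample. "exact" enumerates all
#' feature coalitions (<= 12 features) with absent features marginalized by
#' background averaging; "sampling" uses a seeded Monte-Carlo permutation
#' estimator with the same marginalization. The base value phi0 is the mean
#' model output over the background.
#'
#' @param model function(X) -> numeric, or a \linkS4class{StackedModel}.
#' @param XBackground background sample (matrix/data.frame). Typically a
#'   seeded random fraction (e.g. 10 percent) of the modeled dataset.
#' @param XExplain records to explain; defaults to the background.
#' @param method "auto" (exact up to 12 features), "exact", or "sampling".
#' @param nSamples permutation draws per record for sampling (default 2000).
#' @param seed integer seed for the sampling estimator.
#' @return a \linkS4class{ShapMatrix}.
#' @examples
#' f <- function(X) 2 * X[, 1] - X[, 2]
#' bg <- matrix(0, 2, 2); x <- matrix(c(1, 1), 1)
#' shapPhi(shapValues(f, bg, x))  # (2, -1)
#' @export
shapValues <- function(model, XBackground, XExplain = XBackground,
                       method = c("auto", "exact", "sampling"),
                       nSamples = 2000L, seed = 1L) {
  method <- match.arg(method)
  f <- .predFun(model)
  Xb <- .asFeatureMatrix(XBackground)
  Xe <- .asFeatureMatrix(XExplain)
  if (nrow(Xb) == 0L) stop("empty background set")
  if (!identical(colnames(Xb), colnames(Xe))) {
    stop("background and explained records must share the same features")
  }
  if (method == "auto") {
    method <- if (ncol(Xe) <= 12L) "exact" else "sampling"
  }
  res <- if (method == "exact") {
    .shapExact(f, Xb, Xe)
  } else {
    .shapSampling(f, Xb, Xe, nSamples = nSamples, seed = seed)
  }
  new("ShapMatrix", phi = res$phi, baseValue = res$base, method = method,
      backgroundSpec = list(n_background = nrow(Xb), seed = seed,
                            n_samples = if (method == "sampling") nSamples
                                        else NA_integer_),
      X = as.data.frame(Xe))
}

#' Rank features by mean absolute Shapley attribution
#'
#' @param s a \linkS4class{ShapMatrix}.
#' @return data.frame (descending \code{mean_abs_shap}; ties broken
#'   lexically) with the sign-direction summary \code{frac_positive}.
#' @export
aggregateImportance <- function(s) {
  stopifnot(is(s, "ShapMatrix"))
  phi <- shapPhi(s)
  if (ncol(phi) == 0L) stop("empty attribution matrix")
  df <- data.frame(
    feature = colnames(phi),
    mean_abs_shap = colMeans(abs(phi)),
    frac_positive = colMeans(phi > 0),
    stringsAsFactors = FALSE)
  df <- df[order(-df$mean_abs_shap, df$feature), ]
  rownames(df) <- NULL
  df
}

#' Dependence profile of Shapley attributions on one feature
#'
#' Scatter-ready (feature value, phi) pairs, sorted by feature value, for
#' plots of how a descriptor drives the prediction.
#'
#' @param s a \linkS4class{ShapMatrix}.
#' @param feature feature name.
#' @return data.frame with columns \code{value} and \code{phi}.
#' @export
dependenceProfile <- function(s, feature) {
  stopifnot(is(s, "ShapMatrix"))
  if (!feature %in% colnames(shapPhi(s))) {
    stop("unknown feature: ", feature)
  }
  df <- data.frame(value = s@X[[feature]],
                   phi = shapPhi(s)[, feature])
  df[order(df$value), , drop = FALSE]
}
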
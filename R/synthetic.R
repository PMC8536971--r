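# Seeded synthetic-data generators. They give every pipeline stage an input
# with known ground truth: a pair of overlapping bioactivity sources with a
# configured number of discordant duplicates, a library of valid
# ligand-like SMILES assembled from a fragment grammar, and descriptor ->
# pKi regression benchmarks with a known informative feature set.
#
# Generator defaults mirror the study conditions: pKi drawn from a normal
# distribution with mean 7.0 and sd 1.0 clipped to [4.2, 11.0] (the observed
# activity range), concordant duplicate differences within the 0.1
# threshold, and discordant differences drawn from (threshold, 4.46], the
# observed spread between sources.

.fragmentGrammar <- list(
  sub = c("", "F", "Cl", "Br", "C", "CC", "CO", "O", "N", "FC(F)(F)",
          "N#C", "CS"),
  aryl = c("%sc1ccc(cc1)", "%sc1cccc(c1)", "%sc1ccc2ccccc2c1"),
  linker = c("C", "CC", "CCC", "CCCC", "OCC", "OCCC", "C(=O)", "C(=O)C",
             "CC(=O)", "C(=O)NCC", "S(=O)(=O)CC", "C(C)C", "CCOC", "CCCCC"),
  center = c("N1CCN(CC1)", "N1CCC(CC1)", "C1CCN(CC1)", "N1CCCC1C",
             "N(C)CC", "NCC", "N1CCCCC1", "N(CC)CC", "C1CN(CCN1C)"),
  tail = c("c1ccccc1", "c1ccc(F)cc1", "c1ccc(Cl)cc1", "c1ccc(OC)cc1",
           "c1ccc(C)cc1", "c1ccc2ccccc2c1", "c1cccnc1", "c1ccncc1",
           "c1ccco1", "c1cccs1", "C", "CC", "CCO", "C(=O)C",
           "c1ccc(O)cc1", "CC(C)C")
)

#' Generate a library of valid, distinct ligand-like SMILES
#'
#' Assembles structures from a fragment grammar (substituted aryl head,
#' alkyl/acyl linker, amine/piperazine center, aryl or alkyl tail - echoing
#' common aminergic-ligand chemotypes), canonicalizes them, and keeps unique
#' canonical keys via rejection sampling until \code{n} are collected.
#'
#' @param n number of structures.
#' @param seed integer seed; the output is bit-reproducible.
#' @return character vector of \code{n} distinct canonical SMILES (the
#'   canonical key of each element is the element itself).
#' @examples
#' \dontrun{
#' lib <- genSmilesLibrary(10, seed = 1)
#' }
#' @export
genSmilesLibrary <- function(n, seed = 1L) {
  .assertScalarNumber(n, "n", min = 1)
  g <- .fragmentGrammar
  out <- character(0)
  .withSeed(deriveSeed(seed, "smiles-library"), {
    tries <- 0L
    while (length(out) < n && tries < 60L) {
      m <- max(64L, ceiling((n - length(out)) * 1.5))
      smi <- vapply(seq_len(m), function(i) {
        head <- sprintf(sample(g$aryl, 1), sample(g$sub, 1))
        paste0(head, sample(g$linker, 1), sample(g$center, 1),
               sample(g$tail, 1))
      }, character(1))
      can <- canonicalKey(smi, onError = "na")
      can <- can[!is.na(can)]
      out <- c(out, setdiff(unique(can), out))
      tries <- tries + 1L
    }
  })
  if (length(out) < n) {
    stop("fragment grammar exhausted at ", length(out),
         " unique structures (requested ", n, ")")
  }
  out[seq_len(n)]
}

# draw pKi values: normal(mean, sd) clipped to the configured range
.drawPKi <- function(n, mean = 7, sd = 1, clip = c(4.2, 11.0)) {
  pmin(pmax(stats::rnorm(n, mean, sd), clip[1]), clip[2])
}

#' Generate a pair of overlapping bioactivity sources with known ground truth
#'
#' Emulates two public-database exports of the same assay target: each
#' source holds a configured number of unique structures, \code{nShared} of
#' which occur in both. Shared structures get pKi values differing by at
#' most \code{threshold} except for \code{nDiscordant} designated pairs,
#' whose absolute difference is drawn from (threshold, 4.46]. Curating the
#' output with the same threshold must yield exactly
#' \code{nA + nB - nShared - nDiscordant} entries.
#'
#' @param nA,nB unique compound counts per source.
#' @param nShared structures present in both sources.
#' @param nDiscordant shared structures whose pKi difference exceeds the
#'   threshold.
#' @param threshold concordance threshold in pKi units (default 0.1).
#' @param seed integer seed.
#' @param sourceA,sourceB source labels.
#' @param pKiMean,pKiSd,pKiClip marginal pKi distribution (defaults: normal
#'   with mean 7, sd 1, clipped to [4.2, 11]).
#' @param maxDelta upper bound of the discordant difference (default 4.46).
#' @param smiles optional pre-generated library of distinct canonical
#'   SMILES (at least \code{nA + nB - nShared}); generated when NULL.
#' @return list with \code{a}, \code{b} (\linkS4class{BioactivitySet}s) and
#'   \code{truth} (expected post-curation count and the designated keys).
#' @export
genSources <- function(nA, nB, nShared, nDiscordant, threshold = 0.1,
                       seed = 1L, sourceA = "ZINC", sourceB = "ChEMBL",
                       pKiMean = 7, pKiSd = 1, pKiClip = c(4.2, 11.0),
                       maxDelta = 4.46, smiles = NULL) {
  .assertScalarNumber(nA, "nA", 1); .assertScalarNumber(nB, "nB", 1)
  .assertScalarNumber(nShared, "nShared", 0)
  .assertScalarNumber(nDiscordant, "nDiscordant", 0)
  if (nShared > min(nA, nB)) stop("nShared must be <= min(nA, nB)")
  if (nDiscordant > nShared) stop("nDiscordant must be <= nShared")

  nUnique <- nA + nB - nShared
  if (is.null(smiles)) {
    smiles <- genSmilesLibrary(nUnique, seed = deriveSeed(seed, "structures"))
  }
  if (length(smiles) < nUnique) stop("need at least ", nUnique, " structures")
  smiles <- smiles[seq_len(nUnique)]

  .withSeed(deriveSeed(seed, "activities"), {
    sharedSmi <- smiles[seq_len(nShared)]
    onlyA <- smiles[nShared + seq_len(nA - nShared)]
    onlyB <- smiles[nA + seq_len(nB - nShared)]

    pkiShared <- .drawPKi(nShared, pKiMean, pKiSd, pKiClip)
    # partner values: concordant pairs differ by U[0, threshold], the
    # designated discordant pairs by U(threshold, maxDelta]; the sign points
    # toward the distribution center so values stay plausible
    delta <- c(stats::runif(nDiscordant, threshold, maxDelta),
               stats::runif(nShared - nDiscordant, 0, threshold))
    delta[seq_len(nDiscordant)] <-
      pmax(delta[seq_len(nDiscordant)], threshold + 1e-6)
    sgn <- ifelse(pkiShared > pKiMean, -1, 1)
    pkiSharedB <- pkiShared + sgn * delta

    a <- makeBioactivitySet(
      smiles = c(sharedSmi, onlyA),
      pKi = c(pkiShared, .drawPKi(length(onlyA), pKiMean, pKiSd, pKiClip)),
      sourceId = sourceA, keys = c(sharedSmi, onlyA))
    b <- makeBioactivitySet(
      smiles = c(sharedSmi, onlyB),
      pKi = c(pkiSharedB, .drawPKi(length(onlyB), pKiMean, pKiSd, pKiClip)),
      sourceId = sourceB, keys = c(sharedSmi, onlyB))

    list(a = a, b = b,
         truth = list(
           expected_final = nA + nB - nShared - nDiscordant,
           shared_keys = sharedSmi,
           discordant_keys = sharedSmi[seq_len(nDiscordant)],
           threshold = threshold))
  })
}

#' Generate a descriptor -> pKi regression benchmark
#'
#' Draws a standard-normal feature matrix and computes the response from a
#' known function of the first \code{k} (informative) features, rescaled to
#' the pKi scale (mean 7, unit variance) and clipped to \code{clip}, plus
#' Gaussian noise. The returned ground truth carries the informative set and
#' the noiseless response for oracle checks.
#'
#' @param n records.
#' @param d features.
#' @param k informative features (k <= d).
#' @param form "linear", "additive-nonlinear" (default), or "interaction".
#' @param noiseSd Gaussian noise standard deviation (default 0.5).
#' @param clip response clip range (default c(4.2, 11.0)).
#' @param seed integer seed.
#' @return list with \code{X} (matrix, columns D001..), \code{y}, and
#'   \code{truth} (informative names, noiseless y, functional form).
#' @examples
#' bench <- genQsarDataset(100, 10, 3, seed = 7)
#' range(bench$y)
#' @export
genQsarDataset <- function(n, d, k, form = c("additive-nonlinear", "linear",
                                             "interaction"),
                           noiseSd = 0.5, clip = c(4.2, 11.0), seed = 1L) {
  form <- match.arg(form)
  .assertScalarNumber(n, "n", 1); .assertScalarNumber(d, "d", 1)
  .assertScalarNumber(k, "k", 1); .assertScalarNumber(noiseSd, "noiseSd", 0)
  if (k > d) stop("k must be <= d")

  .withSeed(deriveSeed(seed, "qsar-bench"), {
    X <- matrix(stats::rnorm(n * d), n, d,
                dimnames = list(NULL, sprintf("D%03d", seq_len(d))))
    beta <- stats::runif(k, 0.5, 2) * sample(c(-1, 1), k, replace = TRUE)
    nlFuns <- list(function(x) sin(2 * x), function(x) x^2,
                   function(x) tanh(2 * x), function(x) abs(x),
                   function(x) exp(x / 2))
    y0 <- switch(form,
      linear = drop(X[, seq_len(k), drop = FALSE] %*% beta),
      `additive-nonlinear` = {
        Reduce(`+`, lapply(seq_len(k), function(j) {
          beta[j] * nlFuns[[(j - 1L) %% length(nlFuns) + 1L]](X[, j])
        }))
      },
      interaction = {
        add <- Reduce(`+`, lapply(seq_len(k), function(j) {
          beta[j] * nlFuns[[(j - 1L) %% length(nlFuns) + 1L]](X[, j])
        }))
        if (k >= 2) add + 0.8 * X[, 1] * X[, 2] else add
      })
    mu <- mean(y0); s <- stats::sd(y0)
    if (!is.finite(s) || s == 0) s <- 1
    yClean <- pmin(pmax(7 + (y0 - mu) / s, clip[1]), clip[2])
    y <- yClean
    if (noiseSd > 0) {
      y <- pmin(pmax(yClean + stats::rnorm(n, 0, noiseSd), clip[1]), clip[2])
    }
    list(X = X, y = y,
         truth = list(informative = colnames(X)[seq_len(k)],
                      y_noiseless = yClean, beta = beta, form = form,
                      noise_sd = noiseSd))
  })
}
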
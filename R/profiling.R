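# Exploratory profiling of a curated database: drug-likeness rules
# (Lipinski rule of five, Veber rules), Tanimoto similarity distribution,
# pKi summary, and the Pearson correlation matrix of key descriptors.

#' Lipinski / Veber rule flags for one or more compounds
#'
#' Rule of five: molecular weight below 500 Da, logP below 5, at most 5
#' hydrogen-bond donors and 10 acceptors. Veber rules: polar surface area
#' at most 140 A^2 and fewer than 10 rotatable bonds.
#'
#' @param mw molecular weight (Da).
#' @param slogp Wildman-Crippen logP.
#' @param hbd,hba hydrogen-bond donor/acceptor counts.
#' @param psa topological polar surface area (A^2).
#' @param nrot rotatable bond count.
#' @return data.frame of per-compound flags \code{mw_ok}, \code{logp_ok},
#'   \code{hbd_ok}, \code{hba_ok}, \code{psa_ok}, \code{rot_ok},
#'   \code{lipinski_ok}, \code{veber_ok}.
#' @examples
#' lipinskiVeber(300, 2.0, 1, 4, 80, 4)        # all TRUE
#' lipinskiVeber(500, 2.0, 1, 4, 80, 4)$mw_ok  # FALSE: "below 500" is strict
#' @export
lipinskiVeber <- function(mw, slogp, hbd, hba, psa, nrot) {
  stopifnot(all(hbd >= 0, na.rm = TRUE), all(hba >= 0, na.rm = TRUE),
            all(mw >= 0, na.rm = TRUE), all(psa >= 0, na.rm = TRUE))
  df <- data.frame(
    mw_ok = mw < 500,
    logp_ok = slogp < 5,
    hbd_ok = hbd <= 5,
    hba_ok = hba <= 10,
    psa_ok = psa <= 140,
    rot_ok = nrot < 10)
  df$lipinski_ok <- df$mw_ok & df$logp_ok & df$hbd_ok & df$hba_ok
  df$veber_ok <- df$psa_ok & df$rot_ok
  df
}

#' Drug-likeness report for a descriptor matrix
#'
#' Applies [lipinskiVeber()] to the rule columns of a descriptor matrix
#' (MW, SLogP, nHBDon, nHBAcc, TopoPSA, nRot) and aggregates percentages
#' per rule - the layout of a classic rule-of-five summary table.
#'
#' @param m a \linkS4class{DescriptorMatrix} (or numeric matrix with the
#'   six rule columns).
#' @return list with \code{flags} (per-compound data.frame) and
#'   \code{summary} (data.frame: rule, n_fulfilling, percent).
#' @export
ruleReport <- function(m) {
  vals <- if (is(m, "DescriptorMatrix")) m@values else .asFeatureMatrix(m)
  need <- c("MW", "SLogP", "nHBDon", "nHBAcc", "TopoPSA", "nRot")
  miss <- setdiff(need, colnames(vals))
  if (length(miss)) {
    stop("descriptor matrix is missing rule columns: ",
         paste(miss, collapse = ", "))
  }
  flags <- lipinskiVeber(vals[, "MW"], vals[, "SLogP"], vals[, "nHBDon"],
                         vals[, "nHBAcc"], vals[, "TopoPSA"], vals[, "nRot"])
  rules <- c(mw_ok = "Molecular weight", logp_ok = "LogP",
             hba_ok = "H-bond acceptors", hbd_ok = "H-bond donors",
             lipinski_ok = "Complete Lipinski's rules",
             psa_ok = "Polar Surface Area", rot_ok = "Rotatable Bonds",
             veber_ok = "Complete Veber's rules")
  summary <- data.frame(
    rule = unname(rules),
    n_fulfilling = vapply(names(rules), function(f) sum(flags[[f]],
                                                        na.rm = TRUE),
                          numeric(1)),
    percent = vapply(names(rules), function(f) {
      100 * mean(flags[[f]], na.rm = TRUE)
    }, numeric(1)),
    row.names = NULL)
  list(flags = flags, summary = summary)
}

#' Pairwise Tanimoto similarity summary for a compound set
#'
#' Computes fingerprints for all structures and summarizes the pairwise
#' Tanimoto similarity distribution. All pairs are evaluated up to
#' \code{exactLimit} compounds; above that a seeded random sample of
#' \code{sampleSize} pairs is used (all-pairs grows quadratically: ~4.5e7
#' pairs for ~9400 compounds).
#'
#' @param structures character vector of SMILES (>= 2).
#' @param radius,nbits,mode fingerprint configuration
#'   (see [morganFingerprint()]).
#' @param exactLimit all-pairs threshold (default 2000).
#' @param sampleSize sampled pairs above the threshold (default 1e6).
#' @param seed integer seed for the pair sample.
#' @param breaks histogram breaks (default 20 bins over [0, 1]).
#' @return list with \code{values} (pairwise similarities), \code{min},
#'   \code{median}, \code{max}, \code{histogram} (data.frame), and the
#'   fingerprint configuration in \code{config}.
#' @export
similaritySummary <- function(structures, radius = 2L, nbits = 2048L,
                              mode = c("morgan", "ob-fp2"),
                              exactLimit = 2000L, sampleSize = 1e6,
                              seed = 1L, breaks = seq(0, 1, 0.05)) {
  mode <- match.arg(mode)
  n <- length(structures)
  if (n < 2L) stop("need at least two structures")
  fps <- lapply(structures, morganFingerprint, radius = radius,
                nbits = nbits, mode = mode)
  vals <- if (n <= exactLimit) {
    out <- numeric(n * (n - 1) / 2)
    t <- 0L
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        t <- t + 1L
        out[t] <- tanimoto(fps[[i]], fps[[j]])
      }
    }
    out
  } else {
    .withSeed(deriveSeed(seed, "simpairs"), {
      ii <- sample.int(n, sampleSize, replace = TRUE)
      jj <- sample.int(n, sampleSize, replace = TRUE)
      keep <- ii != jj
      mapply(function(i, j) tanimoto(fps[[i]], fps[[j]]),
             ii[keep], jj[keep])
    })
  }
  hist <- data.frame(
    lower = utils::head(breaks, -1), upper = breaks[-1],
    count = as.integer(table(cut(vals, breaks, include.lowest = TRUE))))
  list(values = vals, min = min(vals), median = stats::median(vals),
       max = max(vals), histogram = hist,
       config = list(mode = mode, radius = radius, nbits = nbits,
                     sampled = n > exactLimit, seed = seed))
}

#' Pearson correlation matrix with explicit degenerate-column flagging
#'
#' @param columns named list (or data.frame) of equal-length numeric
#'   vectors (length >= 3).
#' @return symmetric matrix of Pearson r (unit diagonal); rows/columns of
#'   zero-variance inputs are NA and reported in the
#'   \code{"degenerate"} attribute.
#' @examples
#' correlationMatrix(data.frame(x = 1:3, y = c(1, 3, 2)))["x", "y"]  # 0.5
#' @export
correlationMatrix <- function(columns) {
  df <- as.data.frame(columns)
  if (nrow(df) < 3L) stop("need vectors of length >= 3")
  vars <- vapply(df, stats::var, numeric(1))
  degen <- names(df)[!is.na(vars) & vars == 0]
  r <- suppressWarnings(stats::cor(df))
  diag(r) <- 1
  if (length(degen)) r[degen, ] <- r[, degen] <- NA_real_
  for (d in degen) r[d, d] <- NA_real_
  attr(r, "degenerate") <- degen
  r
}

#' Summary of a pKi distribution
#'
#' @param pKi numeric vector.
#' @param breaks histogram breaks (default 0.25-wide bins spanning range).
#' @return list with \code{n}, \code{min}, \code{max}, \code{mean},
#'   \code{median}, \code{sd}, \code{histogram}.
#' @export
pkiSummary <- function(pKi, breaks = NULL) {
  pKi <- pKi[is.finite(pKi)]
  if (!length(pKi)) stop("no finite pKi values")
  if (is.null(breaks)) {
    breaks <- seq(floor(min(pKi) * 4) / 4, ceiling(max(pKi) * 4) / 4, 0.25)
  }
  hist <- data.frame(
    lower = utils::head(breaks, -1), upper = breaks[-1],
    count = as.integer(table(cut(pKi, breaks, include.lowest = TRUE))))
  list(n = length(pKi), min = min(pKi), max = max(pKi), mean = mean(pKi),
       median = stats::median(pKi), sd = stats::sd(pKi), histogram = hist)
}
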
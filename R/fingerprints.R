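# Circular (Morgan/ECFP-style) fingerprints on the parsed molecular graph,
# and the Tanimoto set-overlap coefficient.

# deterministic integer hash mixing (31-bit arithmetic kept exact in
# doubles)
.mix <- function(h, x) {
  (h * 1000003 + x) %% 2147483647
}

#' Morgan (circular) fingerprint of a structure
#'
#' Iterative neighborhood hashing: atom invariants (element, heavy degree,
#' H count, charge, ring membership, aromaticity) are refined \code{radius}
#' times with the sorted (bond order, neighbor hash) environment; all
#' intermediate hashes are folded into \code{nbits} bits.
#'
#' @param smiles a single SMILES string.
#' @param radius neighborhood radius (default 2, ECFP4-like).
#' @param nbits fingerprint length (default 2048).
#' @param mode "morgan" (default) or "ob-fp2" for Open Babel's path-based
#'   FP2 fingerprint.
#' @return sorted integer vector of set bit positions (0-based).
#' @export
morganFingerprint <- function(smiles, radius = 2L, nbits = 2048L,
                              mode = c("morgan", "ob-fp2")) {
  mode <- match.arg(mode)
  if (mode == "ob-fp2") return(.obFP2(smiles, nbits))
  g <- parseSmiles(smiles)
  ctx <- list(nb = .neighborList(g))
  ringAtom <- .ringAtomMask(g)
  nA <- nrow(g$atoms)
  ordmap <- matrix(0, nA, nA)
  b <- g$bonds
  if (nrow(b)) {
    ordmap[cbind(b$a1, b$a2)] <- b$order * 10
    ordmap[cbind(b$a2, b$a1)] <- b$order * 10
  }
  h <- vapply(seq_len(nA), function(i) {
    v <- 17
    v <- .mix(v, .elemProp(g$atoms$elem[i], "Z"))
    v <- .mix(v, length(ctx$nb[[i]]))
    v <- .mix(v, g$atoms$nH[i])
    v <- .mix(v, g$atoms$charge[i] + 10)
    v <- .mix(v, as.integer(ringAtom[i]))
    .mix(v, as.integer(g$atoms$arom[i]))
  }, numeric(1))
  bits <- h %% nbits
  for (r in seq_len(radius)) {
    h2 <- numeric(nA)
    for (i in seq_len(nA)) {
      env <- sort(vapply(ctx$nb[[i]], function(j) {
        .mix(ordmap[i, j], h[j])
      }, numeric(1)))
      v <- .mix(31, h[i])
      for (e in env) v <- .mix(v, e)
      h2[i] <- v
    }
    h <- h2
    bits <- c(bits, h %% nbits)
  }
  sort(unique(as.integer(bits)))
}

.obFP2 <- function(smiles, nbits = 2048L) {
  sdf <- ChemmineR::smiles2sdf(stats::setNames(smiles, "m"))
  fp <- as.matrix(ChemmineR::fingerprintOB(sdf, "FP2"))
  bits <- sort(which(fp[1, ] != 0) - 1L)
  as.integer(bits %% nbits)
}

#' Tanimoto similarity of two bit sets
#'
#' |A intersect B| / |A union B|.
#'
#' @param fpA,fpB integer vectors of set bit positions (or logical
#'   vectors).
#' @return similarity in [0, 1].
#' @examples
#' tanimoto(c(1, 2, 3), c(2, 3, 4))  # 0.5
#' @export
tanimoto <- function(fpA, fpB) {
  if (is.logical(fpA)) fpA <- which(fpA)
  if (is.logical(fpB)) fpB <- which(fpB)
  if (length(fpA) == 0L && length(fpB) == 0L) {
    stop("Tanimoto similarity is undefined for two empty fingerprints")
  }
  length(intersect(fpA, fpB)) / length(union(fpA, fpB))
}
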
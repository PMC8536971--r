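# shared helpers: mock super-learner candidates and small record sets

mockCandidate <- function(id, family, oof, predictFun = NULL) {
  list(id = id, family = family, oof = oof,
       predict = predictFun %||% function(X) rep(mean(oof), nrow(X)),
       cvRmse = sqrt(mean((oof - oof)^2)), cvR2 = NA_real_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# record set built from plain canonical-SMILES keys (no chemistry needed)
keyedSet <- function(keys, pKi, source) {
  makeBioactivitySet(smiles = keys, pKi = pKi, sourceId = source,
                     keys = keys)
}

# brute-force curation oracle: independent set arithmetic on two keyed sets
bruteForceCurationCount <- function(a, b, threshold) {
  ra <- records(a); rb <- records(b)
  shared <- intersect(ra$structure_key, rb$structure_key)
  disc <- sum(abs(ra$pKi[match(shared, ra$structure_key)] -
                  rb$pKi[match(shared, rb$structure_key)]) > threshold)
  nrow(ra) + nrow(rb) - length(shared) - disc
}
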
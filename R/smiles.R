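# Minimal SMILES reader producing the molecular graph the descriptor engine
# works on. It targets the canonical SMILES emitted by Open Babel (which is
# what canonicalKey() produces), i.e. organic-subset atoms, bracket atoms
# with isotope / chirality / H-count / charge, ring-bond closures including
# %nn, branches, bond symbols - = # : / \ and dot-separated components.
# Aromaticity is taken from the lowercase notation (the canonicalizer has
# already perceived it); aromatic bonds carry order 1.5.

.bondOrderChar <- c("-" = 1, "=" = 2, "#" = 3, ":" = 1.5, "/" = 1, "\\" = 1)

#' Parse a SMILES string into a molecular graph
#'
#' Returns a light-weight graph representation: an atom table (element,
#' aromatic flag, formal charge, explicit/implicit hydrogen count) and a bond
#' table (atom indices and bond order, 1.5 for aromatic). Implicit hydrogen
#' counts follow the standard SMILES valence model; bracket atoms use their
#' explicit H count.
#'
#' @param smiles a single SMILES string.
#' @return a list with elements \code{atoms} (data.frame: \code{elem},
#'   \code{arom}, \code{charge}, \code{nH}) and \code{bonds} (data.frame:
#'   \code{a1}, \code{a2}, \code{order}).
#' @examples
#' g <- parseSmiles("CC(=O)Nc1ccc(O)cc1")
#' nrow(g$atoms)
#' @export
parseSmiles <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L, !is.na(smiles))
  s <- trimws(smiles)
  if (nchar(s) == 0L) stop("empty SMILES string")

  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(chars)

  elem <- character(0); arom <- logical(0); charge <- integer(0)
  hExp <- integer(0)   # explicit H from bracket, NA when implicit
  a1 <- integer(0); a2 <- integer(0); ord <- numeric(0)

  prev <- 0L                 # index of atom to bond the next atom to
  stack <- integer(0)        # branch stack
  pendingOrder <- NA_real_   # bond symbol seen since last atom
  ringOpen <- list()         # closure digit -> list(atom, order)

  addAtom <- function(el, ar, ch, hx) {
    elem[length(elem) + 1L] <<- el
    arom[length(arom) + 1L] <<- ar
    charge[length(charge) + 1L] <<- ch
    hExp[length(hExp) + 1L] <<- hx
    length(elem)
  }
  addBond <- function(i, j, o) {
    a1[length(a1) + 1L] <<- i
    a2[length(a2) + 1L] <<- j
    ord[length(ord) + 1L] <<- o
  }
  connect <- function(idx) {
    if (prev > 0L) {
      o <- pendingOrder
      if (is.na(o)) o <- if (arom[prev] && arom[idx]) 1.5 else 1
      addBond(prev, idx, o)
    }
    prev <<- idx
    pendingOrder <<- NA_real_
  }
  closeRing <- function(key) {
    if (!is.null(ringOpen[[key]])) {
      op <- ringOpen[[key]]
      o <- pendingOrder
      if (is.na(o)) o <- op$order
      if (is.na(o)) o <- if (arom[op$atom] && arom[prev]) 1.5 else 1
      addBond(op$atom, prev, o)
      ringOpen[[key]] <<- NULL
    } else {
      ringOpen[[key]] <<- list(atom = prev, order = pendingOrder)
    }
    pendingOrder <<- NA_real_
  }

  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i + 1L
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) stop("unclosed bracket atom in SMILES: ", smiles)
      body <- paste(chars[(i + 1L):(j - 1L)], collapse = "")
      at <- .parseBracketAtom(body, smiles)
      idx <- addAtom(at$elem, at$arom, at$charge, at$nH)
      connect(idx)
      i <- j + 1L
    } else if (ch %in% c("C", "B", "N", "O", "P", "S", "F", "I")) {
      two <- if (i < n) paste0(ch, chars[i + 1L]) else ""
      if (two %in% c("Cl", "Br", "Si")) {
        idx <- addAtom(two, FALSE, 0L, NA_integer_)
        i <- i + 2L
      } else {
        idx <- addAtom(ch, FALSE, 0L, NA_integer_)
        i <- i + 1L
      }
      connect(idx)
    } else if (ch %in% c("c", "n", "o", "s", "p", "b")) {
      idx <- addAtom(toupper(ch), TRUE, 0L, NA_integer_)
      connect(idx)
      i <- i + 1L
    } else if (ch %in% names(.bondOrderChar)) {
      pendingOrder <- unname(.bondOrderChar[ch])
      i <- i + 1L
    } else if (ch == "(") {
      stack <- c(stack, prev)
      i <- i + 1L
    } else if (ch == ")") {
      if (length(stack) == 0L) stop("unbalanced parenthesis in SMILES: ", smiles)
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
      i <- i + 1L
    } else if (grepl("[0-9]", ch)) {
      closeRing(ch)
      i <- i + 1L
    } else if (ch == "%") {
      if (i + 2L > n) stop("truncated %nn ring closure in SMILES: ", smiles)
      closeRing(paste0(chars[i + 1L], chars[i + 2L]))
      i <- i + 3L
    } else if (ch == ".") {
      prev <- 0L
      pendingOrder <- NA_real_
      i <- i + 1L
    } else {
      stop("unsupported SMILES token '", ch, "' in: ", smiles)
    }
  }
  if (length(ringOpen) > 0L && any(!vapply(ringOpen, is.null, logical(1))))
    stop("unmatched ring closure in SMILES: ", smiles)
  if (length(elem) == 0L) stop("no atoms parsed from SMILES: ", smiles)

  atoms <- data.frame(elem = elem, arom = arom, charge = charge,
                      nH = hExp, stringsAsFactors = FALSE)
  bonds <- if (length(a1)) {
    data.frame(a1 = a1, a2 = a2, order = ord)
  } else {
    data.frame(a1 = integer(0), a2 = integer(0), order = numeric(0))
  }
  atoms$nH <- .implicitHydrogens(atoms, bonds)
  list(atoms = atoms, bonds = bonds, smiles = smiles)
}

# body of a bracket atom, e.g. "nH+", "13CH3", "O-", "C@@H"
.parseBracketAtom <- function(body, smiles) {
  m <- regmatches(body, regexec(
    "^([0-9]*)([A-Za-z][a-z]?)(@{0,2})(H[0-9]*)?([+-][0-9]*|[+]+|[-]+)?([:][0-9]+)?$",
    body))[[1]]
  if (length(m) == 0L) stop("cannot parse bracket atom [", body, "] in: ", smiles)
  sym <- m[3]
  ar <- sym == tolower(sym) && !grepl("^[A-Z]", sym)
  el <- paste0(toupper(substr(sym, 1, 1)), substring(sym, 2))
  nH <- 0L
  if (nzchar(m[5])) {
    hn <- sub("^H", "", m[5])
    nH <- if (nzchar(hn)) as.integer(hn) else 1L
  }
  chg <- 0L
  if (nzchar(m[6])) {
    cs <- m[6]
    if (grepl("^[+-][0-9]+$", cs)) {
      chg <- as.integer(cs)
    } else {
      chg <- (nchar(cs)) * (if (substr(cs, 1, 1) == "+") 1L else -1L)
    }
  }
  list(elem = el, arom = ar, charge = chg, nH = nH)
}

# Standard-valence implicit hydrogen model. Aromatic bonds count 1.5 towards
# the bond-order sum, which is then rounded up (so an aromatic CH in benzene
# has used valence 3 and one implicit H).
.implicitHydrogens <- function(atoms, bonds) {
  nA <- nrow(atoms)
  used <- numeric(nA)
  if (nrow(bonds)) {
    for (k in seq_len(nrow(bonds))) {
      used[bonds$a1[k]] <- used[bonds$a1[k]] + bonds$order[k]
      used[bonds$a2[k]] <- used[bonds$a2[k]] + bonds$order[k]
    }
  }
  out <- atoms$nH
  for (i in seq_len(nA)) {
    if (!is.na(out[i])) next   # bracket atom: explicit H count
    vals <- .defaultValences[[atoms$elem[i]]]
    if (is.null(vals)) { out[i] <- 0L; next }
    u <- ceiling(used[i] - 1e-9)
    # aromatic atoms never promote to a higher valence state (an aromatic
    # nitrogen with three ring/substituent connections carries no H)
    v <- if (atoms$arom[i]) vals[1] else vals[vals >= u][1]
    out[i] <- if (is.na(v) || v < u) 0L else as.integer(v - u)
  }
  as.integer(out)
}
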
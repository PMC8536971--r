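# Native 2D molecular descriptor engine, part 1: the per-molecule context
# (graph, distances, rings, kekulized orders, atomic property vectors) and
# the counting / matrix-spectrum / autocorrelation descriptor families.
# Definitions follow the standard 2D descriptor literature conventions
# (Moreau-Broto/Moran/Geary autocorrelations on the hydrogen-included graph,
# Kier-Hall electrotopological states, Galvez charge indices, Ertl polar
# surface contributions, Kier shape indices, Basak information indices).

# ---- kekulization ----------------------------------------------------------

# Assign alternating double bonds within aromatic systems: an aromatic atom
# "needs" a double bond when its sigma valence (all bonds as single + H)
# falls short of its charge-adjusted default valence. A backtracking perfect
# matching over aromatic bonds between needy atoms yields the kekulized
# orders; non-aromatic bonds keep their parsed order.
.kekulize <- function(g) {
  ord <- g$bonds$order
  aromB <- which(ord == 1.5)
  if (!length(aromB)) return(ord)
  nA <- nrow(g$atoms)
  # used valence counting real bond orders, aromatic bonds as single
  sigma <- numeric(nA)
  for (k in seq_len(nrow(g$bonds))) {
    o <- if (ord[k] == 1.5) 1 else ord[k]
    sigma[g$bonds$a1[k]] <- sigma[g$bonds$a1[k]] + o
    sigma[g$bonds$a2[k]] <- sigma[g$bonds$a2[k]] + o
  }
  sigma <- sigma + g$atoms$nH
  target <- vapply(seq_len(nA), function(i) {
    el <- g$atoms$elem[i]; ch <- g$atoms$charge[i]
    base <- switch(el, C = 4, N = 3, O = 2, S = 2, P = 3, B = 3, 6)
    base + if (el %in% c("N", "O", "S", "P")) ch else 0
  }, numeric(1))
  needs <- g$atoms$arom & (target - sigma >= 1)

  kek <- ord
  kek[aromB] <- 1
  matched <- rep(FALSE, nA)
  bondsAt <- lapply(seq_len(nA), function(i) {
    aromB[g$bonds$a1[aromB] == i | g$bonds$a2[aromB] == i]
  })
  needy <- which(needs)
  assign <- function(pos) {
    if (pos > length(needy)) return(TRUE)
    i <- needy[pos]
    if (matched[i]) return(assign(pos + 1L))
    for (bk in bondsAt[[i]]) {
      j <- if (g$bonds$a1[bk] == i) g$bonds$a2[bk] else g$bonds$a1[bk]
      if (needs[j] && !matched[j]) {
        matched[i] <<- TRUE; matched[j] <<- TRUE; kek[bk] <<- 2
        if (assign(pos + 1L)) return(TRUE)
        matched[i] <<- FALSE; matched[j] <<- FALSE; kek[bk] <<- 1
      }
    }
    FALSE
  }
  ok <- assign(1L)
  if (!ok) kek[aromB] <- 1.5   # give up: leave aromatic orders
  kek
}

# ---- per-molecule context --------------------------------------------------

.molContext <- function(g) {
  nA <- nrow(g$atoms)
  deg <- .heavyDegree(g)
  D <- .distMatrix(g)
  connected <- all(is.finite(D))
  rings <- .sssr(g)
  fused <- .fusedRingSystems(rings)
  ringB <- .ringBondMask(g)
  kek <- .kekulize(g)
  Hx <- .expandHydrogens(g, D)
  nb <- .neighborList(g)

  # per-atom bond-order tallies (heavy bonds only)
  nSing <- nDoub <- nTrip <- nArom <- integer(nA)
  for (k in seq_len(nrow(g$bonds))) {
    o <- g$bonds$order[k]
    for (i in c(g$bonds$a1[k], g$bonds$a2[k])) {
      if (o == 1) nSing[i] <- nSing[i] + 1L
      else if (o == 2) nDoub[i] <- nDoub[i] + 1L
      else if (o == 3) nTrip[i] <- nTrip[i] + 1L
      else nArom[i] <- nArom[i] + 1L
    }
  }

  elem <- g$atoms$elem
  Z <- .elemProp(elem, "Z")
  Zv <- .elemProp(elem, "nouter")
  period <- .elemProp(elem, "period")
  h <- g$atoms$nH
  chg <- g$atoms$charge
  # Kier-Hall valence-electron ratio (used by autocorrelation weight "dv")
  dvKH <- ifelse(Z == 1, 0, (Zv - chg - h) / ((Z - chg) - (Zv - chg) - 1))
  # intrinsic state (autocorrelation weight "s")
  sInt <- ifelse(deg == 0, NA_real_, ((2 / period)^2 * dvKH + 1) / deg)
  # electrotopological state: I with the simple valence-electron count
  # (no charge adjustment), perturbed by all pairs
  dvE <- pmax(Zv - h, 0)
  Ie <- ifelse(deg == 0, NA_real_, ((2 / period)^2 * dvE + 1) / deg)
  estate <- rep(NA_real_, nA)
  if (connected && all(!is.na(Ie))) {
    P <- (D + 1)^2
    diag(P) <- Inf
    estate <- Ie + rowSums(outer(Ie, Ie, `-`) / P)
  }

  list(g = g, nA = nA, deg = deg, D = D, connected = connected,
       rings = rings, fused = fused, ringB = ringB, kek = kek, Hx = Hx,
       nb = nb, nSing = nSing, nDoub = nDoub, nTrip = nTrip, nArom = nArom,
       elem = elem, Z = Z, h = h, chg = chg,
       dvKH = dvKH, sInt = sInt, estate = estate)
}

# H-included atomic property vector for a weight code
.atomPropVec <- function(ctx, code) {
  elems <- ctx$Hx$elem
  switch(code,
    Z = .elemProp(elems, "Z"),
    m = .elemProp(elems, "mass"),
    v = .elemProp(elems, "vdwvol"),
    se = .elemProp(elems, "se"),
    pe = .elemProp(elems, "pe"),
    are = .elemProp(elems, "are"),
    p = .elemProp(elems, "pol"),
    i = .elemProp(elems, "ion"),
    dv = c(ctx$dvKH, rep(0, length(elems) - ctx$nA)),
    d = c(ctx$deg, rep(1, length(elems) - ctx$nA)),
    s = c(ctx$sInt, rep(1, length(elems) - ctx$nA)),
    stop("unknown atomic property: ", code))
}

# ---- simple counting families ---------------------------------------------

.descAtomCounts <- function(ctx) {
  el <- ctx$elem
  nHtot <- sum(ctx$h)
  ringMember <- vapply(seq_len(ctx$nA), function(i) {
    sum(vapply(ctx$rings, function(r) i %in% r, logical(1)))
  }, numeric(1))
  # spiro: atom shared by two rings intersecting in exactly that atom;
  # bridgehead: endpoint of a bridge path shared by two rings (rings whose
  # intersection spans >= 3 atoms, e.g. norbornane - ortho-fused rings
  # sharing one bond do not count)
  spiro <- 0L
  bridgeSet <- integer(0)
  if (length(ctx$rings) >= 2) {
    for (i in which(ringMember >= 2)) {
      rs <- which(vapply(ctx$rings, function(r) i %in% r, logical(1)))
      pairs <- utils::combn(rs, 2)
      inter <- apply(pairs, 2, function(p) {
        length(intersect(ctx$rings[[p[1]]], ctx$rings[[p[2]]]))
      })
      if (any(inter == 1)) spiro <- spiro + 1L
    }
    L <- length(ctx$rings)
    for (i1 in seq_len(L - 1L)) {
      for (i2 in (i1 + 1L):L) {
        inter <- intersect(ctx$rings[[i1]], ctx$rings[[i2]])
        if (length(inter) >= 3) {
          # endpoints of the shared path: members with one neighbour inside
          sharedDeg <- vapply(inter, function(a) {
            sum(ctx$nb[[a]] %in% inter)
          }, numeric(1))
          bridgeSet <- union(bridgeSet, inter[sharedDeg <= 1])
        }
      }
    }
  }
  bridge <- length(bridgeSet)
  c(nAtom = ctx$nA + nHtot, nHeavyAtom = ctx$nA,
    nSpiro = spiro, nBridgehead = bridge,
    nHetero = sum(!el %in% c("C", "H")), nH = nHtot,
    nB = sum(el == "B"), nC = sum(el == "C"), nN = sum(el == "N"),
    nO = sum(el == "O"), nS = sum(el == "S"), nP = sum(el == "P"),
    nF = sum(el == "F"), nCl = sum(el == "Cl"), nBr = sum(el == "Br"),
    nI = sum(el == "I"), nX = sum(el %in% .halogens))
}

.descBondCounts <- function(ctx) {
  o <- ctx$g$bonds$order
  nHtot <- sum(ctx$h)
  kek <- ctx$kek
  c(nBonds = length(o) + nHtot,
    nBondsO = length(o),
    nBondsS = sum(o == 1) + nHtot,
    nBondsD = sum(o == 2),
    nBondsT = sum(o == 3),
    nBondsA = sum(o == 1.5),
    nBondsM = sum(o > 1),
    nBondsKS = sum(kek == 1) + nHtot,
    nBondsKD = sum(kek == 2))
}

.descAromatic <- function(ctx) {
  c(nAromAtom = sum(ctx$g$atoms$arom),
    nAromBond = sum(ctx$g$bonds$order == 1.5))
}

.descWeight <- function(ctx) {
  mwExact <- sum(.elemProp(ctx$elem, "isomass")) +
    sum(ctx$h) * .elemProp("H", "isomass")
  nTot <- ctx$nA + sum(ctx$h)
  c(MW = mwExact, AMW = mwExact / nTot)
}

.descPolarizability <- function(ctx) {
  pv <- .elemProp(ctx$Hx$elem, "pol")
  apol <- sum(pv)
  bpol <- 0
  for (k in seq_len(nrow(ctx$g$bonds))) {
    bpol <- bpol + abs(pv[ctx$g$bonds$a1[k]] - pv[ctx$g$bonds$a2[k]])
  }
  bpol <- bpol + sum(abs(.elemProp(ctx$elem, "pol")[ctx$Hx$parent[-seq_len(ctx$nA)]] -
                           .elemProp("H", "pol")))
  c(apol = apol, bpol = bpol)
}

.descMcGowan <- function(ctx) {
  v <- sum(.elemProp(ctx$Hx$elem, "mcgowan"))
  c(VMcGowan = v - (nrow(ctx$g$bonds) + sum(ctx$h)) * 6.56)
}

.bondiVolumes <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, F = 1.47,
                   Cl = 1.75, Br = 1.85, P = 1.80, S = 1.80, B = 2.13,
                   Si = 2.10)

.descVabc <- function(ctx, ringCounts) {
  r <- .bondiVolumes[ctx$Hx$elem]
  if (anyNA(r)) return(c(Vabc = NA_real_))
  ac <- sum(4 / 3 * pi * r^3)
  nb <- nrow(ctx$g$bonds) + sum(ctx$h)
  c(Vabc = ac - 5.92 * nb - 14.7 * ringCounts[["naRing"]] -
      3.8 * ringCounts[["nARing"]])
}

.descVAdjMat <- function(ctx) {
  m <- nrow(ctx$g$bonds)
  c(VAdjMat = if (m > 0) 1 + log2(m) else NA_real_)
}

.descFragCpx <- function(ctx) {
  A <- ctx$nA; B <- nrow(ctx$g$bonds)
  H <- sum(ctx$elem != "C")
  c(fragCpx = abs(B^2 - A^2 + A) + H / 100)
}

.descABC <- function(ctx) {
  d <- ctx$deg
  abc <- 0; gg <- NA_real_
  b <- ctx$g$bonds
  if (nrow(b)) {
    abc <- sum(sqrt((d[b$a1] + d[b$a2] - 2) / (d[b$a1] * d[b$a2])))
    if (ctx$connected) {
      gg <- 0
      for (k in seq_len(nrow(b))) {
        u <- b$a1[k]; v <- b$a2[k]
        nu <- sum(ctx$D[, u] < ctx$D[, v])
        nv <- sum(ctx$D[, v] < ctx$D[, u])
        if (nu * nv > 0) gg <- gg + sqrt((nu + nv - 2) / (nu * nv))
      }
    }
  }
  c(ABC = abc, ABCGG = gg)
}

.descZagreb <- function(ctx) {
  d <- ctx$deg
  b <- ctx$g$bonds
  z2 <- if (nrow(b)) sum(d[b$a1] * d[b$a2]) else 0
  mz2 <- if (nrow(b)) sum(1 / (d[b$a1] * d[b$a2])) else 0
  c(Zagreb1 = sum(d^2), Zagreb2 = z2,
    mZagreb1 = sum(ifelse(d > 0, 1 / d^2, NA_real_)), mZagreb2 = mz2)
}

.descWiener <- function(ctx) {
  if (!ctx$connected) return(c(WPath = NA_real_, WPol = NA_real_))
  c(WPath = sum(ctx$D) / 2, WPol = sum(ctx$D == 3) / 2)
}

.descTopoIndex <- function(ctx) {
  if (!ctx$connected || ctx$nA < 2) {
    return(c(Diameter = NA_real_, Radius = NA_real_,
             TopoShapeIndex = NA_real_, PetitjeanIndex = NA_real_))
  }
  ecc <- apply(ctx$D, 1, max)
  R <- min(ecc); Dm <- max(ecc)
  c(Diameter = Dm, Radius = R,
    TopoShapeIndex = if (R > 0) (Dm - R) / R else NA_real_,
    PetitjeanIndex = if (Dm > 0) (Dm - R) / Dm else NA_real_)
}

.descEccentric <- function(ctx) {
  if (!ctx$connected) return(c(ECIndex = NA_real_))
  c(ECIndex = sum(apply(ctx$D, 1, max) * ctx$deg))
}

.descBalabanJ <- function(ctx) {
  m <- nrow(ctx$g$bonds)
  if (!ctx$connected || m == 0) return(c(BalabanJ = NA_real_))
  gamma <- m - ctx$nA + 1
  si <- rowSums(ctx$D)
  s <- sum(1 / sqrt(si[ctx$g$bonds$a1] * si[ctx$g$bonds$a2]))
  c(BalabanJ = m / (gamma + 1) * s)
}

# spectral attributes of a symmetric matrix (adjacency or distance)
.matrixSpectrum <- function(M, bonds, nAtoms, suffix) {
  out <- stats::setNames(
    rep(NA_real_, 12),
    paste0(c("SpAbs", "SpMax", "SpDiam", "SpAD", "SpMAD", "LogEE",
             "VE1", "VE2", "VE3", "VR1", "VR2", "VR3"), suffix))
  if (any(!is.finite(M))) return(out)
  eg <- eigen(M, symmetric = TRUE)
  val <- eg$values
  out[1] <- sum(abs(val))
  out[2] <- max(val)
  out[3] <- max(val) - min(val)
  out[4] <- sum(abs(val - mean(val)))
  out[5] <- out[4] / nAtoms
  a <- max(max(val), 0)
  out[6] <- a + log(sum(exp(val - a)) + exp(-a))
  vmax <- eg$vectors[, which.max(val)]
  ve1 <- sum(abs(vmax))
  out[7] <- ve1
  out[8] <- ve1 / nAtoms
  out[9] <- if (ve1 > 0) log(0.1 * nAtoms * ve1) else NA_real_
  if (nrow(bonds)) {
    pr <- vmax[bonds$a1] * vmax[bonds$a2]
    vr1 <- if (all(pr > 0)) sum(pr^-0.5) else NA_real_
    out[10] <- vr1
    out[11] <- vr1 / nAtoms
    out[12] <- if (is.finite(vr1) && vr1 > 0) log(0.1 * nAtoms * vr1) else NA_real_
  }
  out
}

.descSpectra <- function(ctx) {
  A <- matrix(0, ctx$nA, ctx$nA)
  b <- ctx$g$bonds
  if (nrow(b)) {
    A[cbind(b$a1, b$a2)] <- 1
    A[cbind(b$a2, b$a1)] <- 1
  }
  adj <- .matrixSpectrum(A, b, ctx$nA, "_A")
  dst <- if (ctx$connected) .matrixSpectrum(ctx$D, b, ctx$nA, "_D") else
    stats::setNames(rep(NA_real_, 12),
                    paste0(c("SpAbs", "SpMax", "SpDiam", "SpAD", "SpMAD",
                             "LogEE", "VE1", "VE2", "VE3", "VR1", "VR2",
                             "VR3"), "_D"))
  c(adj, dst)
}

# ---- autocorrelation -------------------------------------------------------

.autocorrProps <- c("dv", "d", "s", "Z", "m", "v", "se", "pe", "are", "p", "i")

.descAutocorrelation <- function(ctx, maxLag = 8L, charges = NULL) {
  Dh <- ctx$Hx$D
  nTot <- nrow(Dh)
  out <- numeric(0)
  # pair counts per lag
  gsum <- vapply(0:maxLag, function(k) {
    if (k == 0) nTot else sum(Dh == k) / 2
  }, numeric(1))
  # partial-charge weighting enters only the centered/normalized variants
  props <- c(.autocorrProps, "c")
  for (code in props) {
    centeredOnly <- code == "c"
    w <- if (code == "c") {
      if (is.null(charges) || length(charges) != nTot) rep(NA_real_, nTot)
      else charges
    } else {
      .atomPropVec(ctx, code)
    }
    wc <- w - mean(w)
    bad <- anyNA(w)
    for (k in 0:maxLag) {
      ats <- atsc <- NA_real_
      if (!bad) {
        if (k == 0) {
          ats <- sum(w^2); atsc <- sum(wc^2)
        } else {
          G <- Dh == k
          ats <- 0.5 * as.numeric(t(w) %*% G %*% w)
          atsc <- 0.5 * as.numeric(t(wc) %*% G %*% wc)
        }
      }
      if (!centeredOnly) {
        out[sprintf("ATS%d%s", k, code)] <- ats
        out[sprintf("AATS%d%s", k, code)] <-
          if (gsum[k + 1] > 0) ats / gsum[k + 1] else NA_real_
      }
      out[sprintf("ATSC%d%s", k, code)] <- atsc
      aatsc <- if (gsum[k + 1] > 0) atsc / gsum[k + 1] else NA_real_
      out[sprintf("AATSC%d%s", k, code)] <- aatsc
      if (k >= 1) {
        denom <- sum(wc^2)
        out[sprintf("MATS%d%s", k, code)] <-
          if (!bad && denom > 0) nTot * aatsc / denom else NA_real_
        gats <- NA_real_
        if (!bad && denom > 0 && gsum[k + 1] > 0 && nTot > 1) {
          G <- Dh == k
          num <- sum(G * outer(w, w, `-`)^2) / (4 * gsum[k + 1])
          gats <- num / (denom / (nTot - 1))
        }
        out[sprintf("GATS%d%s", k, code)] <- gats
      }
    }
  }
  out
}

# ---- topological charge (Galvez) ------------------------------------------

.descTopoCharge <- function(ctx, maxOrder = 10L) {
  nms <- c(sprintf("GGI%d", 1:maxOrder), sprintf("JGI%d", 1:maxOrder),
           "JGT10")
  out <- stats::setNames(rep(NA_real_, length(nms)), nms)
  if (!ctx$connected || ctx$nA < 2) return(out)
  A <- matrix(0, ctx$nA, ctx$nA)
  b <- ctx$g$bonds
  if (nrow(b)) { A[cbind(b$a1, b$a2)] <- 1; A[cbind(b$a2, b$a1)] <- 1 }
  D2 <- ctx$D
  D2[D2 != 0] <- D2[D2 != 0]^-2
  diag(D2) <- 0
  M <- A %*% D2
  CT <- M - t(M)
  upper <- upper.tri(ctx$D)
  jgt <- 0
  for (k in seq_len(maxOrder)) {
    sel <- upper & ctx$D == k
    nk <- sum(sel)
    ggi <- sum(abs(CT[sel]))
    out[sprintf("GGI%d", k)] <- ggi
    jgi <- if (nk > 0) ggi / nk else 0
    out[sprintf("JGI%d", k)] <- jgi
    jgt <- jgt + jgi
  }
  out["JGT10"] <- jgt
  out
}

# ---- ring counts -----------------------------------------------------------

.descRingCounts <- function(ctx) {
  arom <- ctx$g$atoms$arom
  el <- ctx$elem
  ringName <- function(greater, order, fused, aflag, hflag) {
    paste0("n", if (greater) "G" else "", if (!is.na(order)) order else "",
           if (fused) "F" else "", aflag, hflag, "Ring")
  }
  classify <- function(ringsList) {
    vapply(ringsList, function(r) {
      c(size = length(r),
        arom = as.integer(all(arom[r])),
        het = as.integer(any(el[r] != "C")))
    }, numeric(3))
  }
  out <- numeric(0)
  for (fused in c(FALSE, TRUE)) {
    rs <- if (fused) ctx$fused else ctx$rings
    cls <- if (length(rs)) classify(rs) else
      matrix(numeric(0), 3, 0, dimnames = list(c("size", "arom", "het")))
    for (aromSel in list(c(NA, ""), c(1, "a"), c(0, "A"))) {
      for (hetSel in list(c(NA, ""), c(1, "H"))) {
        pick <- rep(TRUE, ncol(cls))
        if (!is.na(aromSel[1])) pick <- pick & cls["arom", ] == as.numeric(aromSel[1])
        if (!is.na(hetSel[1])) pick <- pick & cls["het", ] == as.numeric(hetSel[1])
        sizes <- cls["size", pick]
        out[ringName(FALSE, NA, fused, aromSel[2], hetSel[2])] <- length(sizes)
        for (o in (if (fused) 4 else 3):12) {
          out[ringName(FALSE, o, fused, aromSel[2], hetSel[2])] <- sum(sizes == o)
        }
        out[ringName(TRUE, 12, fused, aromSel[2], hetSel[2])] <- sum(sizes >= 12)
      }
    }
  }
  out
}

# ---- carbon types ----------------------------------------------------------

.descCarbonTypes <- function(ctx) {
  isC <- ctx$elem == "C"
  hyb <- ifelse(ctx$nTrip > 0 | ctx$nDoub >= 2, 1L,
                ifelse(ctx$nDoub > 0 | ctx$nArom > 0, 2L, 3L))
  nCneighbors <- vapply(seq_len(ctx$nA), function(i) {
    sum(ctx$elem[ctx$nb[[i]]] == "C")
  }, integer(1))
  out <- c(C1SP1 = sum(isC & hyb == 1 & nCneighbors == 1),
           C2SP1 = sum(isC & hyb == 1 & nCneighbors == 2),
           C1SP2 = sum(isC & hyb == 2 & nCneighbors == 1),
           C2SP2 = sum(isC & hyb == 2 & nCneighbors == 2),
           C3SP2 = sum(isC & hyb == 2 & nCneighbors == 3),
           C1SP3 = sum(isC & hyb == 3 & nCneighbors == 1),
           C2SP3 = sum(isC & hyb == 3 & nCneighbors == 2),
           C3SP3 = sum(isC & hyb == 3 & nCneighbors == 3),
           C4SP3 = sum(isC & hyb == 3 & nCneighbors == 4))
  nSP2 <- sum(isC & hyb == 2); nSP3 <- sum(isC & hyb == 3)
  out["FCSP3"] <- if (sum(isC) > 0) nSP3 / sum(isC) else NA_real_
  out["HybRatio"] <- if (nSP2 + nSP3 > 0) nSP3 / (nSP2 + nSP3) else NA_real_
  out
}

# ---- constitutional sums ---------------------------------------------------

.descConstitutional <- function(ctx) {
  out <- numeric(0)
  nTot <- length(ctx$Hx$elem)
  for (code in c("Z", "m", "v", "se", "pe", "are", "p", "i")) {
    w <- .atomPropVec(ctx, code)
    pc <- switch(code,
      Z = .elemProp("C", "Z"), m = .elemProp("C", "mass"),
      v = .elemProp("C", "vdwvol"), se = .elemProp("C", "se"),
      pe = .elemProp("C", "pe"), are = .elemProp("C", "are"),
      p = .elemProp("C", "pol"), i = .elemProp("C", "ion"))
    out[paste0("S", code)] <- sum(w / pc)
    out[paste0("M", code)] <- sum(w / pc) / nTot
  }
  out
}

# ---- molecular distance edge ----------------------------------------------

.descMDE <- function(ctx) {
  out <- numeric(0)
  specs <- list(C = expand.grid(v1 = 1:4, v2 = 1:4),
                O = expand.grid(v1 = 1:2, v2 = 1:2),
                N = expand.grid(v1 = 1:3, v2 = 1:3))
  for (el in names(specs)) {
    sp <- specs[[el]]
    sp <- sp[sp$v1 <= sp$v2, , drop = FALSE]
    for (r in seq_len(nrow(sp))) {
      v1 <- sp$v1[r]; v2 <- sp$v2[r]
      nm <- sprintf("MDE%s-%d%d", el, v1, v2)
      val <- NA_real_
      if (ctx$connected) {
        idx <- which(ctx$elem == el)
        if (length(idx) >= 1) {
          dists <- c()
          for (ii in idx) for (jj in idx) {
            if (jj <= ii) next
            di <- ctx$deg[ii]; dj <- ctx$deg[jj]
            if ((di == v1 && dj == v2) || (di == v2 && dj == v1)) {
              dists <- c(dists, ctx$D[ii, jj])
            }
          }
          n <- length(dists)
          if (n > 0) val <- n / (prod(dists)^(1 / n))
        }
      }
      out[nm] <- val
    }
  }
  out
}

# ---- walk counts -----------------------------------------------------------

.descWalkCounts <- function(ctx) {
  out <- numeric(0)
  nA <- ctx$nA
  A <- matrix(0, nA, nA)
  b <- ctx$g$bonds
  if (nrow(b)) { A[cbind(b$a1, b$a2)] <- 1; A[cbind(b$a2, b$a1)] <- 1 }
  Ak <- A
  mwc <- numeric(10); srw <- numeric(10)
  for (k in 1:10) {
    if (k > 1) Ak <- Ak %*% A
    mwc[k] <- if (k == 1) 0.5 * sum(Ak) else log(sum(Ak) + 1)
    srw[k] <- log(sum(diag(Ak)) + 1)
  }
  for (k in 1:10) out[sprintf("MWC%02d", k)] <- mwc[k]
  out["TMWC10"] <- nA + sum(mwc)
  for (k in 2:10) out[sprintf("SRW%02d", k)] <- srw[k]
  out["TSRW10"] <- nA + sum(srw)
  out
}
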
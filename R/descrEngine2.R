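# Native 2D molecular descriptor engine, part 2: subgraph-based families
# (connectivity chi, Kier shape, path counts), electrotopological-state
# sums, polar surface area contributions, hydrogen-bond/rotatable-bond/
# acid-base counts, neighborhood information content, and the molecular
# framework ratio.

# ---- connected edge-subgraph enumeration (chi) -----------------------------

# All connected subgraphs with 1..maxK edges, each enumerated exactly once
# via ESU (Wernicke) on the line graph: extend only with higher-indexed
# edges outside the current exclusive neighborhood.
.allEdgeSubgraphs <- function(ctx, maxK) {
  b <- ctx$g$bonds
  m <- nrow(b)
  out <- lapply(seq_len(maxK), function(i) list())
  if (m == 0L) return(out)
  edgesAt <- vector("list", ctx$nA)
  for (e in seq_len(m)) {
    edgesAt[[b$a1[e]]] <- c(edgesAt[[b$a1[e]]], e)
    edgesAt[[b$a2[e]]] <- c(edgesAt[[b$a2[e]]], e)
  }
  enb <- lapply(seq_len(m), function(e) {
    setdiff(unique(c(edgesAt[[b$a1[e]]], edgesAt[[b$a2[e]]])), e)
  })
  extend <- function(S, ext, root, inS, inN) {
    k <- length(S)
    out[[k]][[length(out[[k]]) + 1L]] <<- S
    if (k == maxK) return(invisible(NULL))
    while (length(ext)) {
      u <- ext[1]
      ext <- ext[-1]
      newn <- enb[[u]]
      newn <- newn[newn > root & !inS[newn] & !inN[newn]]
      inS2 <- inS; inS2[u] <- TRUE
      inN2 <- inN; inN2[newn] <- TRUE
      extend(c(S, u), c(ext, newn), root, inS2, inN2)
    }
  }
  for (e in seq_len(m)) {
    inS <- rep(FALSE, m); inS[e] <- TRUE
    ext0 <- enb[[e]][enb[[e]] > e]
    inN <- rep(FALSE, m); inN[ext0] <- TRUE
    extend(e, ext0, e, inS, inN)
  }
  out
}

# classify an edge set: path (all degrees <= 2, no cycle), chain (has a
# cycle), cluster (has a branch, no degree-2 vertex), path_cluster (both)
.classifySubgraph <- function(ctx, edges) {
  b <- ctx$g$bonds
  ends <- c(b$a1[edges], b$a2[edges])
  degs <- tabulate(ends, nbins = ctx$nA)
  atoms <- which(degs > 0L)
  degs <- degs[atoms]
  if (length(edges) >= length(atoms)) {
    return(list(type = "chain", atoms = atoms))
  }
  if (all(degs <= 2L)) return(list(type = "path", atoms = atoms))
  if (any(degs == 2L)) return(list(type = "path_cluster", atoms = atoms))
  list(type = "cluster", atoms = atoms)
}

.descChiKappaPaths <- function(ctx, maxChi = 7L) {
  out <- numeric(0)
  d <- pmax(ctx$deg, 0)
  dv <- ctx$dvKH
  chiSum <- function(atomSets, w) {
    x <- 0
    for (at in atomSets) {
      c0 <- prod(w[at])
      if (is.na(c0) || c0 <= 0) return(NA_real_)
      x <- x + c0^-0.5
    }
    x
  }
  # order 0: single atoms
  sets0 <- as.list(seq_len(ctx$nA))
  for (code in c("d", "dv")) {
    w <- if (code == "d") d else dv
    x <- chiSum(sets0, w)
    out[paste0("Xp-0", code)] <- x
    out[paste0("AXp-0", code)] <- x / length(sets0)
  }
  subBySize <- .allEdgeSubgraphs(ctx, maxChi)
  cls <- lapply(subBySize, function(subs) lapply(subs, .classifySubgraph, ctx = ctx))
  pathCounts <- integer(maxChi)
  for (k in seq_len(maxChi)) {
    byType <- split(lapply(cls[[k]], `[[`, "atoms"),
                    vapply(cls[[k]], `[[`, character(1), "type"))
    pathCounts[k] <- length(byType$path %||% list())
    for (code in c("d", "dv")) {
      w <- if (code == "d") d else dv
      if (k <= 7) {
        sets <- byType$path %||% list()
        x <- chiSum(sets, w)
        out[sprintf("Xp-%d%s", k, code)] <- x
        out[sprintf("AXp-%d%s", k, code)] <-
          if (length(sets)) x / length(sets) else NA_real_
      }
      if (k >= 3 && k <= 7) {
        sets <- byType$chain %||% list()
        out[sprintf("Xch-%d%s", k, code)] <-
          if (length(sets)) chiSum(sets, w) else 0
      }
      if (k >= 3 && k <= 6) {
        sets <- byType$cluster %||% list()
        out[sprintf("Xc-%d%s", k, code)] <-
          if (length(sets)) chiSum(sets, w) else 0
      }
      if (k >= 4 && k <= 6) {
        sets <- byType$path_cluster %||% list()
        out[sprintf("Xpc-%d%s", k, code)] <-
          if (length(sets)) chiSum(sets, w) else 0
      }
    }
  }
  # Kier shape indices from path counts of order 1-3
  A <- ctx$nA
  kier <- function(order, P) {
    Pmin <- A - order
    Pmax <- switch(order,
      `1` = 0.5 * A * (A - 1),
      `2` = 0.5 * (A - 1) * (A - 2),
      `3` = if (A %% 2 == 0) 0.25 * (A - 2)^2 else 0.25 * (A - 1) * (A - 3))
    mult <- if (order == 3) 4 else 2
    if (P > 0) mult * Pmax * Pmin / P^2 else NA_real_
  }
  out["Kier1"] <- kier(1L, pathCounts[1])
  out["Kier2"] <- kier(2L, pathCounts[2])
  out["Kier3"] <- kier(3L, pathCounts[3])
  out
}

# ---- simple path enumeration (path counts, molecular id) -------------------

# counts and pi-order products of simple paths with exactly k bonds
.simplePaths <- function(ctx, maxLen = 10L) {
  b <- ctx$g$bonds
  ordmap <- matrix(0, ctx$nA, ctx$nA)
  if (nrow(b)) {
    ordmap[cbind(b$a1, b$a2)] <- b$order
    ordmap[cbind(b$a2, b$a1)] <- b$order
  }
  counts <- integer(maxLen)
  piSum <- numeric(maxLen)
  nb <- ctx$nb
  walk <- function(path, last, w) {
    len <- length(path) - 1L
    if (len > 0) {
      # count undirected paths once: only when endpoint > start
      if (path[length(path)] > path[1]) {
        counts[len] <<- counts[len] + 1L
        piSum[len] <<- piSum[len] + w
      }
    }
    if (len == maxLen) return(invisible(NULL))
    for (nx in nb[[last]]) {
      if (!nx %in% path) {
        walk(c(path, nx), nx, w * ordmap[last, nx])
      }
    }
  }
  for (st in seq_len(ctx$nA)) walk(st, st, 1)
  # undirected dedup is handled by endpoint ordering, but symmetric paths
  # (same start/end impossible in simple path) are fine
  list(counts = counts, piSum = piSum)
}

.descPathCounts <- function(ctx, paths) {
  out <- numeric(0)
  for (k in 2:10) out[sprintf("MPC%d", k)] <- paths$counts[k]
  out["TMPC10"] <- ctx$nA + sum(paths$counts)
  for (k in 1:10) out[sprintf("piPC%d", k)] <- log(paths$piSum[k] + 1)
  out["TpiPC10"] <- log(ctx$nA + sum(paths$piSum) + 1)
  out
}

# ---- electrotopological state ----------------------------------------------

.esTypes <- c(
  "sLi", "ssBe", "ssssBe", "ssBH", "sssB", "ssssB", "sCH3", "dCH2", "ssCH2",
  "tCH", "dsCH", "aaCH", "sssCH", "ddC", "tsC", "dssC", "aasC", "aaaC",
  "ssssC", "sNH3", "sNH2", "ssNH2", "dNH", "ssNH", "aaNH", "tN", "sssNH",
  "dsN", "aaN", "sssN", "ddsN", "aasN", "ssssN", "sOH", "dO", "ssO", "aaO",
  "sF", "sSiH3", "ssSiH2", "sssSiH", "ssssSi", "sPH2", "ssPH", "sssP",
  "dsssP", "sssssP", "sSH", "dS", "ssS", "aaS", "dssS", "ddssS", "sCl",
  "sGeH3", "ssGeH2", "sssGeH", "ssssGe", "sAsH2", "ssAsH", "sssAs",
  "sssdAs", "sssssAs", "sSeH", "dSe", "ssSe", "aaSe", "dssSe", "ddssSe",
  "sBr", "sSnH3", "ssSnH2", "sssSnH", "ssssSn", "sI", "sPbH3", "ssPbH2",
  "sssPbH", "ssssPb")

.estateAtomType <- function(ctx, i) {
  na <- ctx$nArom[i]; nt <- ctx$nTrip[i]
  nd <- ctx$nDoub[i]; ns <- ctx$nSing[i]
  h <- ctx$h[i]
  # charge-separated nitro N is typed as its hypervalent form (ddsN)
  if (ctx$elem[i] == "N" && ctx$chg[i] == 1 && nd >= 1) {
    b <- ctx$g$bonds
    for (k in which((b$a1 == i | b$a2 == i) & b$order == 1)) {
      j <- if (b$a1[k] == i) b$a2[k] else b$a1[k]
      if (ctx$elem[j] == "O" && ctx$chg[j] == -1) {
        nd <- nd + 1L; ns <- ns - 1L
        break
      }
    }
  }
  pre <- paste0(strrep("a", na), strrep("t", nt), strrep("d", nd),
                strrep("s", ns))
  suf <- if (h > 0) paste0("H", if (h > 1) h else "") else ""
  paste0(pre, ctx$elem[i], suf)
}

.descEState <- function(ctx) {
  types <- vapply(seq_len(ctx$nA), .estateAtomType, character(1), ctx = ctx)
  out <- numeric(0)
  for (tp in .esTypes) {
    idx <- which(types == tp)
    es <- ctx$estate[idx]
    out[paste0("N", tp)] <- length(idx)
    out[paste0("S", tp)] <- if (length(idx)) sum(es) else 0
    out[paste0("MAX", tp)] <- if (length(idx)) max(es) else NA_real_
    out[paste0("MIN", tp)] <- if (length(idx)) min(es) else NA_real_
  }
  out
}

# ---- Ertl topological polar surface area ----------------------------------

.tpsaContrib <- function(ctx, i) {
  el <- ctx$elem[i]
  if (!el %in% c("N", "O", "S", "P")) return(c(0, 0))
  na <- ctx$nArom[i]; nt <- ctx$nTrip[i]; nd <- ctx$nDoub[i]
  ns <- ctx$nSing[i]; h <- ctx$h[i]; ch <- ctx$chg[i]
  arom <- ctx$g$atoms$arom[i]
  in3ring <- any(vapply(ctx$rings, function(r) length(r) == 3 && i %in% r,
                        logical(1)))
  key <- paste(el, arom, ch, h, ns, nd, nt, na, sep = "|")
  val <- 0
  if (el == "N") {
    val <-
      if (arom) {
        if (ch == 0 && h == 0 && na == 2 && ns == 0 && nd == 0) 12.89
        else if (ch == 0 && h == 0 && na == 3) 4.41
        else if (ch == 0 && h == 0 && na == 2 && ns == 1) 4.93
        else if (ch == 0 && h == 0 && na == 2 && nd == 1) 8.39
        else if (ch == 0 && h == 1 && na == 2) 15.79
        else if (ch == 1 && h == 0 && na == 3) 4.10
        else if (ch == 1 && h == 0 && na == 2 && ns == 1) 3.88
        else if (ch == 1 && h == 1 && na == 2) 14.14
        else 30.5 - 8.2 * (ns + nd + nt + na + h) + 1.5 * h   # generic fallback
      } else if (ch == 0) {
        if (h == 0 && ns == 3 && nd == 0 && nt == 0) { if (in3ring) 3.01 else 3.24 }
        else if (h == 0 && ns == 1 && nd == 1) 12.36
        else if (h == 0 && nt == 1 && ns == 0) 23.79
        else if (h == 0 && ns == 1 && nd == 2) 11.68
        else if (h == 0 && nd == 1 && nt == 1) 13.60
        else if (h == 1 && ns == 2) { if (in3ring) 21.94 else 12.03 }
        else if (h == 1 && nd == 1 && ns == 0) 23.85
        else if (h == 2 && ns == 1) 26.02
        else max(0, 30.5 - 8.2 * (ns + 2 * nd + 3 * nt) + 1.5 * h)
      } else if (ch == 1) {
        if (h == 0 && ns == 4) 0.00
        else if (h == 0 && ns == 2 && nd == 1) 3.01
        else if (h == 0 && nt == 1 && ns == 1) 4.36
        else if (h == 1 && ns == 3) 4.44
        else if (h == 1 && ns == 1 && nd == 1) 13.97
        else if (h == 2 && ns == 2) 16.61
        else if (h == 2 && nd == 1) 25.59
        else if (h == 3 && ns == 1) 27.64
        else 0
      } else 0
  } else if (el == "O") {
    val <-
      if (arom) 13.14
      else if (ch == 0) {
        if (h == 0 && ns == 2) { if (in3ring) 12.53 else 9.23 }
        else if (h == 0 && nd == 1) 17.07
        else if (h == 1 && ns == 1) 20.23
        else 0
      } else if (ch == -1 && ns == 1) 23.06
      else 0
    return(c(val, val))   # O counts in both NO-only and full PSA
  } else if (el == "S") {
    val <-
      if (arom) {
        if (nd == 1) 21.70 else 28.24
      } else if (ch == 0) {
        if (h == 1 && ns == 1) 38.80
        else if (h == 0 && ns == 2 && nd == 0) 25.30
        else if (h == 0 && nd == 1 && ns == 0) 32.09
        else if (h == 0 && ns == 2 && nd == 1) 19.21
        else if (h == 0 && ns == 2 && nd == 2) 8.38
        else 0
      } else 0
    return(c(0, val))
  } else if (el == "P") {
    val <-
      if (ch != 0 || arom) 0
      else if (h == 0 && ns == 3 && nd == 0) 13.59
      else if (h == 0 && ns == 1 && nd == 1) 34.14
      else if (h == 0 && ns == 3 && nd == 1) 9.81
      else if (h == 1 && ns == 2 && nd == 1) 23.47
      else 0
    return(c(0, val))
  }
  c(val, val)   # N contributes to both
}

.descTopoPSA <- function(ctx) {
  tot <- c(0, 0)
  for (i in seq_len(ctx$nA)) tot <- tot + .tpsaContrib(ctx, i)
  c(`TopoPSA(NO)` = tot[1], TopoPSA = tot[2])
}

# ---- hydrogen bond donors / acceptors --------------------------------------

.descHBond <- function(ctx) {
  el <- ctx$elem; h <- ctx$h; ch <- ctx$chg
  arom <- ctx$g$atoms$arom
  b <- ctx$g$bonds
  # donors: N or O carrying at least one hydrogen
  don <- sum((el == "N" | el == "O") & h > 0)
  # neighbour of i that is conjugated: single-bonded atom bearing a double
  # bond to O/N/P/S (the acid-OH / amide-N exclusion pattern *-*=[O,N,P,S])
  conjNeighbor <- function(i) {
    for (k in which((b$a1 == i | b$a2 == i) & b$order == 1)) {
      j <- if (b$a1[k] == i) b$a2[k] else b$a1[k]
      for (k2 in which((b$a1 == j | b$a2 == j) & b$order == 2)) {
        j2 <- if (b$a1[k2] == j) b$a2[k2] else b$a1[k2]
        if (el[j2] %in% c("O", "N", "P", "S")) return(TRUE)
      }
    }
    FALSE
  }
  acc <- 0L
  for (i in seq_len(ctx$nA)) {
    if (!el[i] %in% c("N", "O", "S")) next
    valence <- ctx$nSing[i] + 2 * ctx$nDoub[i] + 3 * ctx$nTrip[i] +
      1.5 * ctx$nArom[i] + h[i]
    if (arom[i]) {
      # aromatic n (no H), o, s - all neutral-charge acceptors
      if (ch[i] == 0 && (el[i] != "N" || h[i] == 0)) acc <- acc + 1L
      next
    }
    if (ch[i] < 0 && el[i] %in% c("O", "S")) { acc <- acc + 1L; next }
    if (ch[i] != 0) next
    if (el[i] == "N") {
      # trivalent N not adjacent to a conjugating group (amide excluded)
      if (round(valence) == 3 && !conjNeighbor(i)) acc <- acc + 1L
    } else {
      # O/S of total valence 2 (ethers, carbonyls, thioethers); hydroxyl /
      # thiol only when not attached to a conjugated carbon (acids excluded)
      if (round(valence) == 2) {
        if (h[i] >= 1 && conjNeighbor(i)) next
        acc <- acc + 1L
      }
    }
  }
  c(nHBAcc = acc, nHBDon = don)
}

# ---- rotatable bonds (strict: amide-like bonds excluded) -------------------

.descRotatable <- function(ctx) {
  b <- ctx$g$bonds
  el <- ctx$elem
  inTriple <- ctx$nTrip > 0
  nRot <- 0L
  amideC <- function(j) {
    # carbon/sulfur with a double bond to O (amide / sulfonyl pattern)
    if (!el[j] %in% c("C", "S")) return(FALSE)
    for (k2 in which((b$a1 == j | b$a2 == j) & b$order == 2)) {
      j2 <- if (b$a1[k2] == j) b$a2[k2] else b$a1[k2]
      if (el[j2] == "O") return(TRUE)
    }
    FALSE
  }
  # symmetric top: atom whose other neighbours are >= 3 identical terminal
  # atoms (CF3, tert-butyl) - rotation is degenerate
  symTop <- function(i, j) {
    others <- setdiff(ctx$nb[[i]], j)
    length(others) >= 3 && all(ctx$deg[others] == 1) &&
      length(unique(el[others])) == 1
  }
  for (k in seq_len(nrow(b))) {
    if (b$order[k] != 1 || ctx$ringB[k]) next
    i <- b$a1[k]; j <- b$a2[k]
    if (ctx$deg[i] < 2 || ctx$deg[j] < 2) next
    if (inTriple[i] || inTriple[j]) next
    # strict: exclude amide/ester/sulfonamide bonds C(=O)-[N,O], S(=O)(=O)-N
    if ((el[i] %in% c("N", "O") && amideC(j)) ||
        (el[j] %in% c("N", "O") && amideC(i))) next
    if (symTop(i, j) || symTop(j, i)) next
    nRot <- nRot + 1L
  }
  nBondsO <- nrow(b)
  c(nRot = nRot,
    RotRatio = if (nBondsO > 0) nRot / nBondsO else NA_real_)
}

# ---- acidic / basic group counts ------------------------------------------

.descAcidBase <- function(ctx) {
  el <- ctx$elem; h <- ctx$h; ch <- ctx$chg
  b <- ctx$g$bonds
  nAcid <- 0L; nBase <- 0L
  singleNb <- function(i) {
    ks <- which((b$a1 == i | b$a2 == i) & b$order == 1)
    vapply(ks, function(k) if (b$a1[k] == i) b$a2[k] else b$a1[k], integer(1))
  }
  doubleNb <- function(i) {
    ks <- which((b$a1 == i | b$a2 == i) & b$order == 2)
    vapply(ks, function(k) if (b$a1[k] == i) b$a2[k] else b$a1[k], integer(1))
  }
  sp3C <- function(j) {
    el[j] == "C" && !ctx$g$atoms$arom[j] && ctx$nDoub[j] == 0 &&
      ctx$nTrip[j] == 0
  }
  chargedNb <- function(i, sign) {
    any(vapply(ctx$nb[[i]], function(j) sign * ch[j] > 0, logical(1)))
  }
  for (i in seq_len(ctx$nA)) {
    # acidic: O(H) single-bonded to C/S/P which has =O
    if (el[i] == "O" && h[i] == 1 && ch[i] == 0) {
      for (j in singleNb(i)) {
        if (el[j] %in% c("C", "S", "P") &&
            any(el[doubleNb(j)] == "O")) {
          nAcid <- nAcid + 1L
          break
        }
      }
    }
    # anionic site (zwitterionic/ylide pairs like nitro excluded)
    if (ch[i] < 0 && !chargedNb(i, 1)) nAcid <- nAcid + 1L
    # basic: amine N bonded only to sp3 carbons, or amidine N, or cation
    if (ch[i] > 0) {
      if (!chargedNb(i, -1)) nBase <- nBase + 1L
      next
    }
    if (el[i] == "N" && !ctx$g$atoms$arom[i] && ctx$nTrip[i] == 0) {
      sn <- singleNb(i)
      if (ctx$nDoub[i] == 0 && length(sn) == ctx$deg[i] &&
          length(sn) > 0 && all(vapply(sn, sp3C, logical(1))) &&
          length(sn) + h[i] == 3) {
        nBase <- nBase + 1L
      } else if (ctx$nDoub[i] == 1 && any(el[doubleNb(i)] == "C")) {
        # N=C-N amidine pattern
        jc <- doubleNb(i)[el[doubleNb(i)] == "C"][1]
        if (any(el[singleNb(jc)] == "N")) nBase <- nBase + 1L
      } else if (ctx$nDoub[i] == 0 && length(sn) > 0) {
        # N-C=N other half of amidine
        for (j in sn) {
          if (el[j] == "C" && any(el[doubleNb(j)] == "N")) {
            nBase <- nBase + 1L
            break
          }
        }
      }
    }
  }
  c(nAcid = nAcid, nBase = nBase)
}

# ---- neighborhood information content --------------------------------------

.descInformationContent <- function(ctx, maxOrder = 5L) {
  # equivalence classes on the hydrogen-included graph, refined by
  # (kekulized bond order, neighbour class) multisets
  nA <- ctx$nA
  nH <- sum(ctx$h)
  nTot <- nA + nH
  elems <- ctx$Hx$elem
  Zs <- .elemProp(elems, "Z")
  masses <- .elemProp(elems, "mass")
  parent <- ctx$Hx$parent
  # adjacency with kekulized orders, H expanded
  edges <- list()
  b <- ctx$g$bonds
  for (k in seq_len(nrow(b))) {
    edges[[length(edges) + 1L]] <- c(b$a1[k], b$a2[k], ctx$kek[k])
  }
  hIdx <- if (nTot > nA) (nA + 1L):nTot else integer(0)
  for (hi in hIdx) {
    edges[[length(edges) + 1L]] <- c(parent[hi], hi, 1)
  }
  nbE <- vector("list", nTot)
  for (e in edges) {
    nbE[[e[1]]] <- c(nbE[[e[1]]], list(e[c(3, 2)]))
    nbE[[e[2]]] <- c(nbE[[e[2]]], list(e[c(3, 1)]))
  }
  totDeg <- lengths(nbE)
  out <- numeric(0)
  sumB <- sum(vapply(edges, `[[`, numeric(1), 3))
  shannon <- function(counts, w = 1) {
    -sum(w * (counts / nTot) * log2(counts / nTot))
  }
  atwt <- .elemProp(elems, "atwt")

  # Round-based BFS tree from one root: each round expands every current
  # leaf to its neighbours not yet used as an expansion source; the class
  # label is the sorted set of root-to-leaf trails of (bond order, atomic
  # number, total degree) steps.
  treeCode <- function(root, order) {
    visited <- rep(FALSE, nTot)
    visited[root] <- TRUE
    tree <- list(atom = root, children = NULL)
    expand <- function(node) {
      visited[node$atom] <<- TRUE
      if (is.null(node$children)) {
        kids <- vapply(nbE[[node$atom]], `[[`, numeric(1), 2)
        ords <- vapply(nbE[[node$atom]], `[[`, numeric(1), 1)
        keep <- !visited[kids]
        node$children <- mapply(function(k, o) {
          list(atom = k, bond = o, children = NULL)
        }, kids[keep], ords[keep], SIMPLIFY = FALSE)
      } else {
        node$children <- lapply(node$children, expand)
      }
      node
    }
    for (r in seq_len(order)) tree <- expand(tree)
    trails <- character(0)
    walk <- function(node, trail) {
      lab <- paste0(if (!is.null(node$bond)) paste0(node$bond, ">") else "",
                    Zs[node$atom], ".", totDeg[node$atom])
      trail <- paste0(trail, "|", lab)
      if (is.null(node$children) || length(node$children) == 0L) {
        trails[length(trails) + 1L] <<- trail
      } else {
        for (ch in node$children) walk(ch, trail)
      }
    }
    walk(tree, "")
    paste(sort(trails), collapse = ";")
  }

  for (m in 0:maxOrder) {
    labels <- if (m == 0) as.character(Zs) else
      vapply(seq_len(nTot), treeCode, character(1), order = m)
    tab <- table(labels)
    counts <- as.numeric(tab)
    rep1 <- match(names(tab), labels)   # representative atom per class
    ic <- shannon(counts)
    out[paste0("IC", m)] <- ic
    out[paste0("TIC", m)] <- nTot * ic
    out[paste0("SIC", m)] <- if (nTot > 1) ic / log2(nTot) else NA_real_
    out[paste0("BIC", m)] <- if (sumB > 1) ic / log2(sumB) else NA_real_
    out[paste0("CIC", m)] <- log2(nTot) - ic
    out[paste0("MIC", m)] <- shannon(counts, w = atwt[rep1])
    out[paste0("ZMIC", m)] <- shannon(counts, w = counts * Zs[rep1])
  }
  out
}

# ---- molecular framework ratio ---------------------------------------------

.descFramework <- function(ctx) {
  nTot <- ctx$nA + sum(ctx$h)
  if (!length(ctx$rings)) return(c(fMF = 0))
  ringAtoms <- unique(unlist(ctx$rings))
  linkers <- integer(0)
  if (length(ctx$rings) >= 2 && ctx$connected) {
    # contract each ring to a node; linkers are non-ring atoms on shortest
    # paths between ring systems
    ig <- .molIgraph(ctx$g)
    for (i in seq_len(length(ctx$rings) - 1L)) {
      for (j in (i + 1L):length(ctx$rings)) {
        ri <- ctx$rings[[i]]; rj <- ctx$rings[[j]]
        if (length(intersect(ri, rj))) next
        best <- NULL
        dmin <- Inf
        for (u in ri) {
          du <- ctx$D[u, rj]
          if (min(du) < dmin) {
            dmin <- min(du)
            best <- c(u, rj[which.min(du)])
          }
        }
        if (!is.null(best) && dmin > 1) {
          sp <- suppressWarnings(igraph::shortest_paths(
            ig, from = as.character(best[1]),
            to = as.character(best[2]))$vpath[[1]])
          mid <- setdiff(as.integer(igraph::as_ids(sp)), ringAtoms)
          linkers <- union(linkers, mid)
        }
      }
    }
  }
  c(fMF = (length(ringAtoms) + length(linkers)) / nTot)
}

# ---- drug-likeness booleans ------------------------------------------------

.descFilters <- function(mw, slogp, smr, hbd, hba, natoms) {
  lip <- as.numeric(!is.na(slogp) && hbd <= 5 && hba <= 10 && mw <= 500 &&
                      slogp <= 5)
  gho <- as.numeric(!is.na(slogp) && !is.na(smr) &&
                      mw >= 160 && mw <= 480 && natoms >= 20 && natoms <= 70 &&
                      slogp >= -0.4 && slogp <= 5.6 && smr >= 40 && smr <= 130)
  c(Lipinski = lip, GhoseFilter = gho)
}
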
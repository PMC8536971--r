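# Graph utilities over the parsed molecule: topological distances, ring
# perception (smallest set of smallest rings), and the hydrogen-included
# expansion used by descriptors that weight hydrogens explicitly.

.molIgraph <- function(g) {
  igraph::graph_from_data_frame(
    d = if (nrow(g$bonds)) g$bonds[, c("a1", "a2")] else
      data.frame(a1 = integer(0), a2 = integer(0)),
    directed = FALSE,
    vertices = data.frame(name = seq_len(nrow(g$atoms)))
  )
}

# topological distance matrix between heavy atoms (Inf across components)
.distMatrix <- function(g) {
  ig <- .molIgraph(g)
  d <- igraph::distances(ig)
  o <- order(as.integer(rownames(d)))
  d[o, o, drop = FALSE]
}

# indices of bonds participating in a ring (non-bridge edges)
.ringBondMask <- function(g) {
  nb <- nrow(g$bonds)
  if (nb == 0L) return(logical(0))
  ig <- .molIgraph(g)
  br <- igraph::bridges(ig)
  mask <- rep(TRUE, nb)
  if (length(br)) {
    ends <- igraph::ends(ig, br)
    for (k in seq_len(nrow(ends))) {
      i <- as.integer(ends[k, 1]); j <- as.integer(ends[k, 2])
      hit <- which((g$bonds$a1 == i & g$bonds$a2 == j) |
                   (g$bonds$a1 == j & g$bonds$a2 == i))
      mask[hit] <- FALSE
    }
  }
  mask
}

.ringAtomMask <- function(g) {
  mask <- rep(FALSE, nrow(g$atoms))
  rb <- .ringBondMask(g)
  if (any(rb)) {
    mask[unique(c(g$bonds$a1[rb], g$bonds$a2[rb]))] <- TRUE
  }
  mask
}

# Smallest set of smallest rings via a greedy minimum cycle basis: candidate
# smallest cycles through every ring bond, selected in order of length under
# GF(2) linear independence until the cyclomatic number is reached.
.sssr <- function(g) {
  nb <- nrow(g$bonds)
  nA <- nrow(g$atoms)
  if (nb == 0L) return(list())
  ig <- .molIgraph(g)
  comps <- igraph::components(ig)$no
  rank <- nb - nA + comps
  if (rank <= 0L) return(list())

  rb <- which(.ringBondMask(g))
  cand <- list()
  for (k in rb) {
    i <- g$bonds$a1[k]; j <- g$bonds$a2[k]
    ig2 <- igraph::delete_edges(
      ig, igraph::get_edge_ids(ig, c(as.character(i), as.character(j))))
    sp <- suppressWarnings(igraph::shortest_paths(
      ig2, from = as.character(i), to = as.character(j))$vpath[[1]])
    if (length(sp) == 0L) next
    cyc <- as.integer(igraph::as_ids(sp))
    cand[[length(cand) + 1L]] <- cyc
  }
  if (!length(cand)) return(list())
  cand <- cand[!duplicated(lapply(cand, function(x) sort(x)))]
  cand <- cand[order(lengths(cand))]

  # edge incidence vectors over GF(2)
  edgeId <- function(i, j) {
    which((g$bonds$a1 == i & g$bonds$a2 == j) |
          (g$bonds$a1 == j & g$bonds$a2 == i))[1]
  }
  toVec <- function(cyc) {
    v <- integer(nb)
    m <- length(cyc)
    for (t in seq_len(m)) {
      e <- edgeId(cyc[t], cyc[if (t == m) 1L else t + 1L])
      v[e] <- 1L
    }
    v
  }
  basis <- matrix(integer(0), nrow = 0, ncol = nb)
  rings <- list()
  for (cyc in cand) {
    v <- toVec(cyc)
    w <- v
    if (nrow(basis)) {
      for (r in seq_len(nrow(basis))) {
        piv <- which(basis[r, ] == 1L)[1]
        if (w[piv] == 1L) w <- (w + basis[r, ]) %% 2L
      }
    }
    if (any(w == 1L)) {
      piv <- which(w == 1L)[1]
      ordr <- order(apply(rbind(basis, w), 1, function(x) which(x == 1L)[1]))
      basis <- rbind(basis, w)[ordr, , drop = FALSE]
      rings[[length(rings) + 1L]] <- cyc
      if (length(rings) == rank) break
    }
  }
  rings
}

# fused ring systems: unions of SSSR rings sharing >= 2 atoms
.fusedRingSystems <- function(rings) {
  L <- length(rings)
  if (L < 2L) return(list())
  adj <- matrix(FALSE, L, L)
  for (i in seq_len(L - 1L)) {
    for (j in (i + 1L):L) {
      if (length(intersect(rings[[i]], rings[[j]])) >= 2L) {
        adj[i, j] <- adj[j, i] <- TRUE
      }
    }
  }
  gg <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  memb <- igraph::components(gg)$membership
  out <- list()
  for (cmp in unique(memb)) {
    ids <- which(memb == cmp)
    if (length(ids) >= 2L) {
      out[[length(out) + 1L]] <- sort(unique(unlist(rings[ids])))
    }
  }
  out
}

# Hydrogen-included expansion: appends one pseudo-atom per implicit H.
# Distances to an H are its parent's distance + 1; H atoms on the same parent
# are at distance 2.
.expandHydrogens <- function(g, dmat = NULL) {
  if (is.null(dmat)) dmat <- .distMatrix(g)
  nA <- nrow(g$atoms)
  nHs <- g$atoms$nH
  parents <- rep(seq_len(nA), nHs)
  nTot <- nA + length(parents)
  elems <- c(g$atoms$elem, rep("H", length(parents)))
  D <- matrix(0, nTot, nTot)
  D[seq_len(nA), seq_len(nA)] <- dmat
  if (length(parents)) {
    hIdx <- nA + seq_along(parents)
    D[seq_len(nA), hIdx] <- dmat[, parents, drop = FALSE] + 1
    D[hIdx, seq_len(nA)] <- t(dmat[, parents, drop = FALSE] + 1)
    D[hIdx, hIdx] <- dmat[parents, parents, drop = FALSE] + 2
    diag(D) <- 0
  }
  list(elem = elems, parent = c(seq_len(nA), parents), D = D, nHeavy = nA)
}

# heavy-atom degree (number of heavy neighbours) per atom
.heavyDegree <- function(g) {
  deg <- integer(nrow(g$atoms))
  if (nrow(g$bonds)) {
    tab <- table(factor(c(g$bonds$a1, g$bonds$a2), levels = seq_len(nrow(g$atoms))))
    deg <- as.integer(tab)
  }
  deg
}

# neighbour list per atom
.neighborList <- function(g) {
  nA <- nrow(g$atoms)
  nb <- vector("list", nA)
  for (k in seq_len(nrow(g$bonds))) {
    i <- g$bonds$a1[k]; j <- g$bonds$a2[k]
    nb[[i]] <- c(nb[[i]], j)
    nb[[j]] <- c(nb[[j]], i)
  }
  nb
}
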
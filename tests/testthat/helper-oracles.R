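## Independent oracles and small fixture builders. Everything here is kept
## deliberately naive (enumeration, grids, direct formulas) so it cannot
## share defects with the package's production path.

aaLetters <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F",
               "P","S","T","W","Y","V")

randomAlignment <- function(tipLabels, nCol, seed) {
  set.seed(seed)
  seqs <- vapply(tipLabels, function(t)
    paste0(sample(aaLetters, nCol, TRUE), collapse = ""), character(1L))
  proteinAlignment(seqs)
}

## Alignment simulated under the stationary model itself (all node
## compositions equal to the model frequencies).
stationaryAlignment <- function(tree, model, nCol, seed) {
  nn <- ape::Ntip(tree) + tree$Nnode
  freqs <- matrix(equilibriumFreqs(model), nn, 20L, byrow = TRUE)
  simulateAlignment(tree, freqs, nCol,
                    exchangeabilities = model@exchangeabilities,
                    alpha = model@alpha, k = model@k, seed = seed)
}

## Exhaustive-enumeration likelihood and marginal posteriors: sums over all
## 20^m internal-state assignments, mixing rate categories with equal
## priors. Leaves must be gap-free.
enumOracle <- function(tree, aln, model) {
  n <- ape::Ntip(tree); m <- tree$Nnode
  edges <- tree$edge; lens <- tree$edge.length
  k <- model@k; rates <- categoryRates(model)
  chars <- alignmentMatrix(aln)
  S <- ncol(chars)
  tipState <- vapply(tree$tip.label, function(t)
    match(chars[match(t, alignmentIds(aln)), ], aaLetters), integer(S))
  grid <- as.matrix(expand.grid(rep(list(1:20), m)))
  freqs <- equilibriumFreqs(model)
  colLog <- numeric(S)
  post <- lapply(seq_len(m), function(i) matrix(0, S, 20L))
  for (s in seq_len(S)) {
    likCat <- numeric(k)
    postCat <- array(0, c(m, 20L, k))
    for (c in seq_len(k)) {
      P <- lapply(seq_len(nrow(edges)), function(e)
        transitionMatrix(model, lens[e] * rates[c]))
      st <- integer(n + m)
      st[seq_len(n)] <- tipState[s, ]
      w <- apply(grid, 1L, function(g) {
        st[(n + 1L):(n + m)] <- g
        pr <- freqs[g[1L]]           # root = node n+1 = grid column 1
        for (e in seq_len(nrow(edges)))
          pr <- pr * P[[e]][st[edges[e, 1L]], st[edges[e, 2L]]]
        pr
      })
      likCat[c] <- sum(w)
      for (j in seq_len(m))
        postCat[j, , c] <- vapply(1:20, function(a)
          sum(w[grid[, j] == a]), numeric(1L))
    }
    colLog[s] <- log(mean(likCat))
    for (j in seq_len(m))
      post[[j]][s, ] <- rowSums(matrix(postCat[j, , ], 20L, k)) / sum(likCat)
  }
  names(post) <- treeNodeIds(tree)[(n + 1L):(n + m)]
  for (j in seq_len(m)) colnames(post[[j]]) <- aaLetters
  list(logLik = sum(colLog), posteriors = post)
}

## Grid-search MAD branch score: evaluates the RMS deviation on a dense
## grid of root positions, deriving every pair's ancestor from nodepath().
gridMadScore <- function(tree, e, nGrid = 1e4) {
  D <- ape::dist.nodes(tree)
  n <- ape::Ntip(tree)
  u <- tree$edge[e, 1L]; v <- tree$edge[e, 2L]
  len <- tree$edge.length[e]
  pairs <- t(utils::combn(n, 2L))
  onPath <- apply(pairs, 1L, function(p) {
    np <- ape::nodepath(tree, p[1L], p[2L])
    any(np == u) && any(np == v) &&
      abs(which(np == u) - which(np == v)) == 1L
  })
  xs <- seq(0, len, length.out = nGrid)
  devSq <- matrix(0, nrow(pairs), nGrid)
  for (i in seq_len(nrow(pairs))) {
    b <- pairs[i, 1L]; c2 <- pairs[i, 2L]
    dbc <- D[b, c2]
    if (onPath[i]) {
      ## ancestor is the root point itself
      dToB <- pmin(D[u, b] + xs, D[v, b] + (len - xs))
      devSq[i, ] <- (2 * dToB / dbc - 1)^2
    } else {
      ## ancestor: the path node nearest the root edge (same for all x)
      np <- ape::nodepath(tree, b, c2)
      anc <- np[which.min(vapply(np, function(p)
        min(D[p, u], D[p, v]), numeric(1L)))]
      devSq[i, ] <- (2 * D[anc, b] / dbc - 1)^2
    }
  }
  score <- sqrt(colMeans(devSq))
  list(x = xs[which.min(score)], score = min(score))
}

## Non-clocklike 6-leaf fixture used by several MAD tests.
madFixtureTree <- function() {
  readNewick(text = paste0("((A:0.13,B:0.62):0.35,(C:0.09,(D:0.41,E:0.22)",
                           ":0.51):0.18,F:0.77);"))
}
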
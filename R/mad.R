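#' Pairwise leaf-to-leaf path distances
#'
#' Sum of branch lengths along the unique path between each pair of leaves.
#'
#' @param tree an \code{ape::phylo} with branch lengths.
#' @return symmetric matrix with leaf labels as dimnames.
#' @export
pairwiseLeafDistances <- function(tree) {
  validatePhyloTree(tree)
  D <- ape::dist.nodes(tree)
  n <- ape::Ntip(tree)
  out <- D[seq_len(n), seq_len(n), drop = FALSE]
  dimnames(out) <- list(tree$tip.label, tree$tip.label)
  out
}

## Leaf sets below every node in ape's edge orientation.
.leafSets <- function(tree) {
  n <- ape::Ntip(tree)
  sets <- vector("list", n + tree$Nnode)
  for (i in seq_len(n)) sets[[i]] <- i
  po <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(po$edge))) {
    u <- po$edge[e, 1L]; v <- po$edge[e, 2L]
    sets[[u]] <- c(sets[[u]], sets[[v]])
  }
  sets
}

#' Score a branch as a root position by minimal ancestor deviation
#'
#' For a putative root at distance x from the branch's first endpoint, each
#' leaf pair contributes a relative deviation from the molecular-clock
#' expectation that its ancestor lies midway: for pairs spanning the branch
#' the ancestor is the root itself and the deviation is
#' |2 (d(i,b) + x) / d(b,c) - 1|; for same-side pairs the ancestor is the
#' fixed node where their paths meet. x is the closed-form minimiser of the
#' spanning pairs' summed squared deviations, clamped to the branch. The
#' score is the root-mean-square deviation over all leaf pairs.
#'
#' @param tree an \code{ape::phylo} (treated as unrooted).
#' @param branch edge index into \code{tree$edge}.
#' @param D optional precomputed \code{ape::dist.nodes(tree)} matrix.
#' @param leafSets optional precomputed per-node leaf sets.
#' @return list with \code{branch}, \code{x} (distance from
#'   \code{tree$edge[branch, 1]}), and \code{score}.
#' @seealso [madRoot()]
#' @export
scoreRootBranch <- function(tree, branch, D = NULL, leafSets = NULL) {
  if (is.null(D)) D <- ape::dist.nodes(tree)
  if (is.null(leafSets)) leafSets <- .leafSets(tree)
  n <- ape::Ntip(tree)
  u <- tree$edge[branch, 1L]; v <- tree$edge[branch, 2L]
  len <- tree$edge.length[branch]
  sideV <- leafSets[[v]]
  sideU <- setdiff(seq_len(n), sideV)

  du <- D[u, sideU]                       # endpoint-to-leaf, own side
  dv <- D[v, sideV]
  dbc <- outer(du, dv, "+") + len         # spanning-pair path lengths
  if (any(dbc == 0)) {
    w <- which(dbc == 0, arr.ind = TRUE)[1L, ]
    stop("degenerate leaf pair at zero distance: ",
         tree$tip.label[sideU[w[1L]]], " / ", tree$tip.label[sideV[w[2L]]])
  }
  dum <- matrix(du, length(du), length(dv))
  if (len > 0) {
    x <- sum((dbc - 2 * dum) / dbc^2) / (2 * sum(1 / dbc^2))
    x <- min(max(x, 0), len)
  } else x <- 0
  devSpan <- 2 * (dum + x) / dbc - 1

  ## same-side pairs: ancestor fixed where the two paths meet; the relative
  ## deviation reduces to (d(a,b) - d(a,c)) / d(b,c) for anchor a on root side
  sameDevs <- function(side, anchor) {
    if (length(side) < 2L) return(numeric())
    da <- D[anchor, side]
    dd <- D[side, side, drop = FALSE]
    iu <- which(upper.tri(dd), arr.ind = TRUE)
    dbc2 <- dd[iu]
    if (any(dbc2 == 0)) {
      w <- iu[which(dbc2 == 0)[1L], ]
      stop("degenerate leaf pair at zero distance: ",
           tree$tip.label[side[w[1L]]], " / ", tree$tip.label[side[w[2L]]])
    }
    (da[iu[, 1L]] - da[iu[, 2L]]) / dbc2
  }
  devs <- c(as.numeric(devSpan), sameDevs(sideU, u), sameDevs(sideV, v))
  list(branch = branch, x = x, score = sqrt(mean(devs^2)))
}

#' Root a tree by minimal ancestor deviation (MAD)
#'
#' Evaluates every branch as a candidate root position, places the root at
#' the global minimum-deviation point (splitting the branch into two edges
#' of lengths x and length - x) and reports all candidates ranked by score
#' together with the root ambiguity index (best score / second-best score,
#' in (0, 1]; values near 1 mean an ambiguous root). Ties are broken by the
#' smallest branch index.
#'
#' @param tree an \code{ape::phylo} with >= 3 leaves; a rooted input is
#'   unrooted first.
#' @return list with \code{tree} (rooted \code{phylo}), \code{candidates}
#'   (data.frame branch, x, score, rank) and \code{ambiguity}.
#' @examples
#' tr <- readNewick(text = "((A:1,B:1):1,(C:1,D:1):1);")
#' rooted <- madRoot(tr)$tree
#' @export
madRoot <- function(tree) {
  validatePhyloTree(tree)
  if (ape::Ntip(tree) < 3L) stop("MAD rooting needs at least 3 leaves")
  if (ape::is.rooted(tree)) tree <- ape::unroot(tree)
  n <- ape::Ntip(tree)
  if (sum(tree$edge.length) <= 0) stop("positive total tree length required")
  D <- ape::dist.nodes(tree)
  ls <- .leafSets(tree)
  cand <- lapply(seq_len(nrow(tree$edge)), scoreRootBranch,
                 tree = tree, D = D, leafSets = ls)
  cand <- data.frame(branch = vapply(cand, `[[`, numeric(1L), "branch"),
                     x = vapply(cand, `[[`, numeric(1L), "x"),
                     score = vapply(cand, `[[`, numeric(1L), "score"))
  ord <- order(cand$score, cand$branch)
  cand <- cand[ord, , drop = FALSE]
  cand$rank <- seq_len(nrow(cand))
  rownames(cand) <- NULL
  ambiguity <- if (nrow(cand) > 1L) cand$score[1L] / cand$score[2L] else NA_real_
  rooted <- rootAtEdge(tree, cand$branch[1L], cand$x[1L])
  list(tree = rooted, candidates = cand, ambiguity = ambiguity)
}

#' Root a tree at a point along a branch
#'
#' Inserts a root node on branch \code{e} at distance \code{x} from
#' \code{tree$edge[e, 1]}, splitting it into edges of lengths x and
#' length - x, and reorients all other branches away from the new root.
#' Topology and total branch length are preserved.
#'
#' @param tree an \code{ape::phylo} (rooted or unrooted).
#' @param e edge index.
#' @param x distance from the first endpoint, in [0, branch length].
#' @return A rooted \code{ape::phylo}.
#' @export
rootAtEdge <- function(tree, e, x) {
  validatePhyloTree(tree)
  len <- tree$edge.length[e]
  if (x < 0 || x > len) stop("x must lie within the branch")
  n <- ape::Ntip(tree)
  nOldNode <- tree$Nnode
  ## adjacency over the unrooted graph
  adj <- vector("list", n + nOldNode)
  for (i in seq_len(nrow(tree$edge))) {
    a <- tree$edge[i, 1L]; b <- tree$edge[i, 2L]
    adj[[a]] <- rbind(adj[[a]], c(b, i))
    adj[[b]] <- rbind(adj[[b]], c(a, i))
  }
  u <- tree$edge[e, 1L]; v <- tree$edge[e, 2L]
  oldLabels <- if (!is.null(tree$node.label)) tree$node.label
               else rep("", nOldNode)
  newNum <- integer(n + nOldNode)
  newNum[seq_len(n)] <- seq_len(n)
  nextNode <- n + 1L                      # n+1 is the new root
  edges <- matrix(0L, 0L, 2L)
  lens <- numeric()
  labels <- ""
  ## stack rows: old node, new parent number, incoming length, forbidden edge
  stack <- list(list(u, n + 1L, x, e), list(v, n + 1L, len - x, e))
  while (length(stack)) {
    it <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    node <- it[[1L]]
    if (node > n) {
      nextNode <- nextNode + 1L
      newNum[node] <- nextNode
      labels <- c(labels, oldLabels[node - n])
    }
    edges <- rbind(edges, c(it[[2L]], newNum[node]))
    lens <- c(lens, it[[3L]])
    if (node > n) {
      nb <- adj[[node]]
      for (r in seq_len(nrow(nb))) {
        if (nb[r, 2L] == it[[4L]]) next
        stack[[length(stack) + 1L]] <-
          list(nb[r, 1L], newNum[node], tree$edge.length[nb[r, 2L]], nb[r, 2L])
      }
    }
  }
  out <- list(edge = edges, edge.length = lens, tip.label = tree$tip.label,
              Nnode = nOldNode + 1L, node.label = labels)
  class(out) <- "phylo"
  out <- ape::reorder.phylo(out, "cladewise")
  validatePhyloTree(out, requireRooted = TRUE)
  out
}

#' Write a MAD candidate report
#'
#' @param candidates data.frame from [madRoot()].
#' @param path output TSV.
#' @return Invisibly, \code{path}.
#' @export
writeRootReport <- function(candidates, path) {
  utils::write.table(candidates, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
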
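## ---- internal pruning machinery ------------------------------------------

## Leaf likelihood matrices: 20 x S indicator columns; gaps and ambiguity
## codes are missing data (all-ones columns).
.leafPartials <- function(tree, alignment) {
  m <- alignmentMatrix(alignment)
  miss <- setdiff(tree$tip.label, alignmentIds(alignment))
  if (length(miss)) stop("leaf without sequence: ", miss[1L])
  lapply(tree$tip.label, function(tip) {
    ch <- m[match(tip, alignmentIds(alignment)), ]
    L <- matrix(0, 20L, length(ch))
    known <- ch %in% .AA
    L[cbind(match(ch[known], .AA), which(known))] <- 1
    L[, !known] <- 1
    L
  })
}

## Children and branch lengths per internal node, plus postorder node order.
.treeIndex <- function(tree) {
  po <- ape::reorder.phylo(tree, "postorder")
  list(parents = unique(po$edge[, 1L]),          # children-first order
       kids = split(seq_len(nrow(tree$edge)), tree$edge[, 1L]),
       edge = tree$edge, len = tree$edge.length,
       nTip = ape::Ntip(tree), nNode = tree$Nnode)
}

## Downward (pruning) pass for all rate categories.
## Returns, per category: partials and per-edge child contributions
## (P_e %*% L_child), per-node cumulative per-column log scalers, and the
## k x S matrix of per-column log-likelihoods.
.downPass <- function(tree, alignment, model, index = NULL,
                      leafL = NULL, needContrib = FALSE) {
  if (!ape::is.rooted(tree))
    stop("a rooted tree is required (root it first, e.g. with madRoot)")
  if (is.null(index)) index <- .treeIndex(tree)
  if (is.null(leafL)) leafL <- .leafPartials(tree, alignment)
  S <- ncol(leafL[[1L]])
  k <- model@k
  root <- index$nTip + 1L
  colLogLik <- matrix(NA_real_, k, S)
  cats <- vector("list", k)
  for (c in seq_len(k)) {
    rate <- model@rates[c]
    partial <- vector("list", index$nTip + index$nNode)
    partial[seq_len(index$nTip)] <- leafL
    logsc <- vector("list", index$nTip + index$nNode)
    contrib <- if (needContrib) vector("list", nrow(index$edge)) else NULL
    for (v in index$parents) {
      L <- 1
      sc <- 0
      for (e in index$kids[[as.character(v)]]) {
        child <- index$edge[e, 2L]
        P <- transitionMatrix(model, index$len[e] * rate)
        cc <- P %*% partial[[child]]
        if (needContrib) contrib[[e]] <- cc
        L <- L * cc
        if (!is.null(logsc[[child]])) sc <- sc + logsc[[child]]
      }
      mx <- apply(L, 2L, max)
      mx[mx == 0] <- 1           # impossible columns stay zero
      L <- L / rep(mx, each = 20L)
      partial[[v]] <- L
      logsc[[v]] <- sc + log(mx)
    }
    lik <- colSums(model@freqs * partial[[root]])
    colLogLik[c, ] <- log(lik) + logsc[[root]]
    cats[[c]] <- list(partial = partial, contrib = contrib)
  }
  list(colLogLik = colLogLik, cats = cats, index = index, S = S)
}

## Mix per-category column log-likelihoods with equal category priors.
.mixColumns <- function(colLogLik) {
  mx <- apply(colLogLik, 2L, max)
  out <- ifelse(is.finite(mx),
                mx + log(colMeans(exp(sweep(colLogLik, 2L, mx)))),
                -Inf)
  out
}

#' Phylogenetic log-likelihood of an alignment (pruning algorithm)
#'
#' Felsenstein's pruning algorithm under a reversible amino-acid model with
#' discrete-gamma rate heterogeneity: per column, the likelihood is averaged
#' over the k equal-probability rate categories. Gaps and ambiguity codes
#' are missing data. Per-node column scaling guards against underflow.
#'
#' @param tree rooted \code{ape::phylo} whose leaf labels appear in the
#'   alignment.
#' @param alignment a [ProteinAlignment-class].
#' @param model a [SubstitutionModel-class].
#' @return The total log-likelihood (may be \code{-Inf}, with a warning, for
#'   data impossible under the tree, e.g. differing residues across a
#'   zero-length path).
#' @seealso [marginalAncestralProfiles()], [estimateAlpha()]
#' @export
treeLogLikelihood <- function(tree, alignment, model) {
  validatePhyloTree(tree, requireRooted = TRUE)
  down <- .downPass(tree, alignment, model)
  col <- .mixColumns(down$colLogLik)
  if (any(!is.finite(col)))
    warning("zero-likelihood column(s): data impossible under this tree ",
            "(degenerate zero-length branches?)")
  sum(col)
}

#' Maximum-likelihood estimate of the gamma shape parameter
#'
#' One-dimensional Brent optimisation of the tree log-likelihood over
#' alpha in [0.02, 100] (tolerance 1e-4). The returned fit is never worse
#' than the model's starting alpha.
#'
#' @param tree rooted \code{ape::phylo}.
#' @param alignment a [ProteinAlignment-class].
#' @param model a [SubstitutionModel-class]; its k is kept.
#' @param interval search interval for alpha.
#' @return list with \code{alpha}, \code{logLik}, \code{boundary} (TRUE when
#'   the optimum sits at the search boundary, with a warning), and
#'   \code{model} updated to the fitted alpha.
#' @export
estimateAlpha <- function(tree, alignment, model, interval = c(0.02, 100)) {
  validatePhyloTree(tree, requireRooted = TRUE)
  index <- .treeIndex(tree)
  leafL <- .leafPartials(tree, alignment)
  ll <- function(a) {
    d <- .downPass(tree, alignment, setAlpha(model, a), index, leafL)
    sum(.mixColumns(d$colLogLik))
  }
  opt <- stats::optimize(ll, interval = interval, maximum = TRUE, tol = 1e-4)
  alpha <- opt$maximum; best <- opt$objective
  ll0 <- ll(model@alpha)
  if (ll0 > best) { alpha <- model@alpha; best <- ll0 }
  boundary <- (interval[2L] - alpha) < 1e-2 * interval[2L] ||
              (alpha - interval[1L]) < 1e-2
  if (boundary)
    warning("alpha estimate at search boundary (", signif(alpha, 4L),
            "): rate homogeneity or too little signal")
  list(alpha = alpha, logLik = best, boundary = boundary,
       model = setAlpha(model, alpha))
}

#' Re-estimate branch lengths by maximum likelihood
#'
#' Coordinate-wise Brent optimisation of each branch length in [0, 20]
#' substitutions/site, sweeping over branches until the log-likelihood gain
#' of a sweep falls below \code{tolerance} (default 1e-3) or \code{maxSweeps}
#' sweeps. The log-likelihood never decreases; a branch move is accepted
#' only if it strictly improves the likelihood, so optimal input lengths
#' (including zero-length branches flanked by identical data) are kept.
#'
#' @param tree rooted \code{ape::phylo}.
#' @param alignment a [ProteinAlignment-class].
#' @param model a [SubstitutionModel-class].
#' @param tolerance sweep-level log-likelihood gain threshold.
#' @param maxSweeps maximum number of sweeps (default 20).
#' @param maxLength upper bound of a single branch length.
#' @return list with \code{tree} (updated lengths), \code{logLik},
#'   \code{sweeps}.
#' @export
optimizeBranchLengths <- function(tree, alignment, model, tolerance = 1e-3,
                                  maxSweeps = 20L, maxLength = 20) {
  validatePhyloTree(tree, requireRooted = TRUE)
  leafL <- .leafPartials(tree, alignment)
  llOf <- function(tr) {
    d <- .downPass(tr, alignment, model, .treeIndex(tr), leafL)
    sum(.mixColumns(d$colLogLik))
  }
  cur <- llOf(tree)
  sweeps <- 0L
  repeat {
    sweeps <- sweeps + 1L
    before <- cur
    for (e in seq_len(nrow(tree$edge))) {
      f <- function(b) {
        tr <- tree; tr$edge.length[e] <- b; llOf(tr)
      }
      opt <- stats::optimize(f, interval = c(0, maxLength), maximum = TRUE,
                             tol = 1e-6)
      if (opt$objective > cur + 1e-12) {
        tree$edge.length[e] <- opt$maximum
        cur <- opt$objective
      }
    }
    if (cur - before < tolerance || sweeps >= maxSweeps) break
  }
  list(tree = tree, logLik = cur, sweeps = sweeps)
}
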
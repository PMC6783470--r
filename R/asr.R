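#' Marginal ancestral sequence reconstruction
#'
#' Empirical-Bayes marginal reconstruction: for every internal node v,
#' column s and residue a, the posterior P(x_v = a | data) is computed by a
#' two-pass algorithm — the downward (pruning) partials combined with
#' upward/outside vectors — and mixed over the discrete-gamma rate
#' categories, whose equal priors are reweighted per column by the category
#' likelihoods. Columns where a leaf carries a gap or ambiguity code are
#' treated as missing data and still reconstructed. The MAP residue per
#' column is recorded with an alphabetical tie-break.
#'
#' @param tree rooted \code{ape::phylo}; reversibility of the model is
#'   required (and enforced by [substitutionModel()]).
#' @param alignment a [ProteinAlignment-class] covering all leaves.
#' @param model a [SubstitutionModel-class].
#' @return An [AncestralProfiles-class] covering every internal node
#'   (including the root), with the total log-likelihood attached.
#' @seealso [expectedCvp()], [treeLogLikelihood()], [runPipeline()]
#' @export
marginalAncestralProfiles <- function(tree, alignment, model) {
  validatePhyloTree(tree, requireRooted = TRUE)
  down <- .downPass(tree, alignment, model, needContrib = TRUE)
  index <- down$index
  S <- down$S
  k <- model@k
  nTip <- index$nTip
  root <- nTip + 1L
  innerNodes <- root:(nTip + index$nNode)

  ## per-column category weights P(c | data): softmax of column log-liks
  mx <- apply(down$colLogLik, 2L, max)
  w <- exp(sweep(down$colLogLik, 2L, mx))
  w <- sweep(w, 2L, colSums(w), "/")          # k x S

  post <- vector("list", length(innerNodes))  # accumulated 20 x S posteriors
  names(post) <- as.character(innerNodes)
  for (v in as.character(innerNodes)) post[[v]] <- matrix(0, 20L, S)

  preParents <- rev(index$parents)            # parents-first (preorder)
  for (c in seq_len(k)) {
    rate <- model@rates[c]
    partial <- down$cats[[c]]$partial
    contrib <- down$cats[[c]]$contrib
    U <- vector("list", nTip + index$nNode)
    U[[root]] <- matrix(model@freqs, 20L, S)
    for (u in preParents) {
      es <- index$kids[[as.character(u)]]
      for (e in es) {
        v <- index$edge[e, 2L]
        if (v <= nTip) next                  # leaf posteriors not needed
        F <- U[[u]]
        for (e2 in setdiff(es, e)) F <- F * contrib[[e2]]
        P <- transitionMatrix(model, index$len[e] * rate)
        Uv <- crossprod(P, F)                # t(P) %*% F
        mxc <- apply(Uv, 2L, max)
        mxc[mxc == 0] <- 1
        U[[v]] <- Uv / rep(mxc, each = 20L)
      }
    }
    for (v in innerNodes) {
      u <- partial[[v]] * U[[v]]
      tot <- colSums(u)
      tot[tot == 0] <- 1
      p <- u / rep(tot, each = 20L)
      post[[as.character(v)]] <- post[[as.character(v)]] +
        p * rep(w[c, ], each = 20L)
    }
  }

  ids <- treeNodeIds(tree)
  azOrd <- order(.AA)
  az <- .AA[azOrd]
  profilesOut <- vector("list", length(innerNodes))
  mapSeq <- character(length(innerNodes))
  mapPost <- vector("list", length(innerNodes))
  for (i in seq_along(innerNodes)) {
    pr <- t(post[[as.character(innerNodes[i])]])
    colnames(pr) <- .AA
    profilesOut[[i]] <- pr
    prAz <- pr[, azOrd, drop = FALSE]
    j <- max.col(prAz, ties.method = "first")  # alphabetical tie-break
    mapSeq[i] <- paste0(az[j], collapse = "")
    mapPost[[i]] <- prAz[cbind(seq_len(S), j)]
  }
  nid <- ids[innerNodes]
  names(profilesOut) <- nid
  names(mapSeq) <- nid
  names(mapPost) <- nid
  methods::new("AncestralProfiles", nodeIds = nid, profiles = profilesOut,
               mapSequences = mapSeq, mapPosteriors = mapPost,
               logLikelihood = sum(.mixColumns(down$colLogLik)))
}

#' Write ancestral reconstruction results
#'
#' TSV of per-node, per-column posteriors plus a FASTA of MAP ancestral
#' sequences.
#'
#' @param profiles an [AncestralProfiles-class].
#' @param tsvPath output TSV (node, column, 20 residue probabilities, MAP
#'   residue, MAP posterior).
#' @param fastaPath optional FASTA of MAP sequences.
#' @return Invisibly, \code{tsvPath}.
#' @export
writeAncestralProfiles <- function(profiles, tsvPath, fastaPath = NULL) {
  rows <- lapply(profiles@nodeIds, function(nd) {
    pr <- profiles@profiles[[nd]]
    data.frame(node = nd, column = seq_len(nrow(pr)),
               round(pr, 6L),
               map = strsplit(profiles@mapSequences[[nd]], "")[[1L]],
               map_posterior = round(profiles@mapPosteriors[[nd]], 6L),
               check.names = FALSE)
  })
  utils::write.table(do.call(rbind, rows), tsvPath, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(fastaPath)) {
    set <- Biostrings::BStringSet(profiles@mapSequences)
    Biostrings::writeXStringSet(set, fastaPath)
  }
  invisible(tsvPath)
}
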
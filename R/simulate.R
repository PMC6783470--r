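## Evaluate expr under a local seed, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit({
      if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

#' Simulate a Yule (pure-birth) tree
#'
#' Topology grown by splitting a uniformly chosen extant lineage until the
#' target leaf count is reached; branch lengths are i.i.d. exponential with
#' the given mean. Tips are labelled t1..tn.
#'
#' @param nLeaves number of leaves, >= 3.
#' @param meanBranchLength mean branch length in substitutions/site, > 0.
#' @param seed optional integer seed (the caller's RNG state is restored).
#' @return A rooted binary \code{ape::phylo} with 2 * nLeaves - 2 edges.
#' @export
simulateYuleTree <- function(nLeaves, meanBranchLength, seed = NULL) {
  if (nLeaves < 3L) stop("nLeaves must be >= 3")
  if (meanBranchLength <= 0) stop("meanBranchLength must be positive")
  .withSeed(seed, {
    parent <- c(NA_integer_, 1L, 1L)       # temp ids; 1 = root
    isLeaf <- c(FALSE, TRUE, TRUE)
    leaves <- c(2L, 3L)
    nextId <- 4L
    while (length(leaves) < nLeaves) {
      pick <- leaves[sample.int(length(leaves), 1L)]
      parent <- c(parent, pick, pick)
      isLeaf[pick] <- FALSE
      isLeaf <- c(isLeaf, TRUE, TRUE)
      leaves <- c(setdiff(leaves, pick), nextId, nextId + 1L)
      nextId <- nextId + 2L
    }
    n <- nLeaves
    newNum <- integer(length(parent))
    newNum[isLeaf] <- seq_len(n)
    newNum[!isLeaf] <- n + seq_len(sum(!isLeaf))   # preorder by construction
    edge <- cbind(newNum[parent[-1L]], newNum[-1L])
    tree <- list(edge = edge,
                 edge.length = stats::rexp(nrow(edge), 1 / meanBranchLength),
                 tip.label = paste0("t", seq_len(n)),
                 Nnode = n - 1L)
    class(tree) <- "phylo"
    tree <- ape::reorder.phylo(tree, "cladewise")
    validatePhyloTree(tree, requireRooted = TRUE)
  })
}

#' Simulate a latent OGT trajectory along a tree
#'
#' Brownian motion on temperature: each child's OGT is its parent's plus a
#' Normal(0, sigma^2 * branch length) step, clamped to the biologically
#' plausible range [5, 110] degC.
#'
#' @param tree rooted \code{ape::phylo}.
#' @param rootOgt OGT at the root, degC.
#' @param sigma diffusion scale, degC per sqrt(unit branch length), >= 0.
#' @param seed optional integer seed.
#' @return named numeric over all nodes (names from [treeNodeIds()]),
#'   indexed by ape node number.
#' @export
simulateOgtTrajectory <- function(tree, rootOgt, sigma, seed = NULL) {
  validatePhyloTree(tree, requireRooted = TRUE)
  if (sigma < 0) stop("sigma must be >= 0")
  .withSeed(seed, {
    n <- ape::Ntip(tree)
    ogt <- numeric(n + tree$Nnode)
    ogt[n + 1L] <- rootOgt
    cw <- ape::reorder.phylo(tree, "cladewise")
    for (e in seq_len(nrow(cw$edge))) {
      p <- cw$edge[e, 1L]; ch <- cw$edge[e, 2L]
      step <- stats::rnorm(1L, 0, sigma * sqrt(cw$edge.length[e]))
      ogt[ch] <- min(max(ogt[p] + step, 5), 110)
    }
    stats::setNames(ogt, treeNodeIds(tree))
  })
}

## Shift mass from the polar to the charged residue class (proportionally
## within each class) so the composition's CvP equals x percentage points.
.compositionForCvp <- function(x, baseFreqs, floor = 1e-4) {
  p <- baseFreqs[.AA] / sum(baseFreqs)
  pc <- sum(p[.AA_CHARGED]); pp <- sum(p[.AA_POLAR])
  f0 <- pc - pp
  delta <- (x / 100 - f0) / 2
  lo <- pc * (floor / min(p[.AA_CHARGED]) - 1)
  hi <- pp * (1 - floor / min(p[.AA_POLAR]))
  if (delta < lo || delta > hi) {
    feas <- 100 * (f0 + 2 * c(lo, hi))
    attr(feas, "problem") <- "cvp"
    stop("target CvP ", signif(x, 6L), " unreachable from these base ",
         "frequencies; feasible CvP interval is [",
         signif(feas[1L], 6L), ", ", signif(feas[2L], 6L), "]")
  }
  p[.AA_CHARGED] <- p[.AA_CHARGED] * (pc + delta) / pc
  p[.AA_POLAR] <- p[.AA_POLAR] * (pp - delta) / pp
  p / sum(p)
}

#' Residue composition realising a target OGT
#'
#' Inverts the linear calibration to the target CvP bias
#' x = (OGT - intercept) / slope, then shifts probability mass from the
#' polar to the charged residue class (proportionally within each class,
#' the 12 unclassified residues untouched) so that the composition's CvP
#' equals x exactly.
#'
#' @param targetOgt target OGT, degC.
#' @param calibration a [CalibrationModel-class] (default the built-in one).
#' @param baseFreqs base equilibrium frequencies (default: LG frequencies).
#' @return named numeric(20) summing to 1. Errors, stating the feasible OGT
#'   interval, if the shift would drive a frequency below 1e-4.
#' @export
compositionForOgt <- function(targetOgt, calibration = defaultCalibration(),
                              baseFreqs = NULL) {
  if (modelSlope(calibration) == 0) stop("calibration slope must be nonzero")
  if (is.null(baseFreqs)) baseFreqs <- .lgFreqs()
  x <- (targetOgt - modelIntercept(calibration)) / modelSlope(calibration)
  out <- tryCatch(.compositionForCvp(x, baseFreqs), error = function(e) e)
  if (inherits(out, "error")) {
    ## restate the feasible interval on the OGT scale
    m <- regmatches(conditionMessage(out),
                    regexec("\\[(-?[0-9.eE+]+), (-?[0-9.eE+]+)\\]",
                            conditionMessage(out)))[[1L]]
    if (length(m) == 3L) {
      lim <- sort(predictOgt(calibration, as.numeric(m[2:3])))
      stop("target OGT ", targetOgt, " degC unreachable from these base ",
           "frequencies; feasible OGT interval is [",
           signif(lim[1L], 6L), ", ", signif(lim[2L], 6L), "] degC")
    }
    stop(out)
  }
  out
}

.lgFreqs <- function() {
  dat <- .readPamlDat(system.file("extdata", "LG.dat",
                                  package = "thermoasr", mustWork = TRUE))
  stats::setNames(dat$freqs, .AA)
}

#' Simulate an alignment along a tree with node-wise compositions
#'
#' Non-stationary sequence simulation: the root sequence is drawn i.i.d.
#' from the root's equilibrium frequencies; along each branch every column
#' evolves under the transition matrix built from the child node's
#' frequencies (shared exchangeabilities, each rate matrix normalised to
#' mean rate 1). Each column's discrete-gamma rate category is drawn once
#' at the root and inherited. No indels; leaves come out ungapped.
#'
#' @param tree rooted \code{ape::phylo}.
#' @param nodeFreqs numeric matrix (Ntip + Nnode rows, 20 columns, rows in
#'   ape node-number order) of per-node equilibrium frequencies.
#' @param nColumns number of columns, >= 1.
#' @param exchangeabilities "LG"/"WAG" or a symmetric 20 x 20 matrix.
#' @param alpha gamma shape of the rate heterogeneity.
#' @param k number of rate categories.
#' @param seed optional integer seed.
#' @return A [SyntheticTruth-class] holding the leaf alignment, every node's
#'   true sequence, the node frequencies, and the simulation parameters.
#' @export
simulateAlignment <- function(tree, nodeFreqs, nColumns,
                              exchangeabilities = "LG", alpha = 1, k = 4L,
                              seed = NULL) {
  validatePhyloTree(tree, requireRooted = TRUE)
  if (nColumns < 1L) stop("nColumns must be >= 1")
  n <- ape::Ntip(tree)
  nn <- n + tree$Nnode
  if (!is.matrix(nodeFreqs) || nrow(nodeFreqs) != nn || ncol(nodeFreqs) != 20L)
    stop("nodeFreqs must be a (Ntip + Nnode) x 20 matrix")
  exch <- if (is.character(exchangeabilities)) {
    .readPamlDat(system.file("extdata", paste0(exchangeabilities, ".dat"),
                             package = "thermoasr", mustWork = TRUE))$R
  } else exchangeabilities
  .withSeed(seed, {
    rates <- discreteGammaRates(alpha, k)
    category <- sample.int(k, nColumns, replace = TRUE)
    states <- matrix(0L, nn, nColumns)
    root <- n + 1L
    states[root, ] <- sample.int(20L, nColumns, replace = TRUE,
                                 prob = nodeFreqs[root, ])
    models <- vector("list", nn)
    cw <- ape::reorder.phylo(tree, "cladewise")
    for (e in seq_len(nrow(cw$edge))) {
      p <- cw$edge[e, 1L]; ch <- cw$edge[e, 2L]
      len <- cw$edge.length[e]
      if (is.null(models[[ch]]))
        models[[ch]] <- substitutionModel(name = "custom",
                                          exchangeabilities = exch,
                                          frequencies = nodeFreqs[ch, ],
                                          alpha = 1, k = 1L)
      for (c in seq_len(k)) {
        cols <- which(category == c)
        if (!length(cols)) next
        P <- transitionMatrix(models[[ch]], len * rates[c])
        ps <- states[p, cols]
        for (a in unique(ps)) {
          sel <- cols[ps == a]
          states[ch, sel] <- sample.int(20L, length(sel), replace = TRUE,
                                        prob = P[a, ])
        }
      }
    }
    ids <- treeNodeIds(tree)
    seqs <- apply(states, 1L, function(s) paste0(.AA[s], collapse = ""))
    names(seqs) <- ids
    aln <- proteinAlignment(seqs[seq_len(n)])
    methods::new("SyntheticTruth", tree = tree,
                 nodeOgt = stats::setNames(numeric(0), character(0)),
                 nodeFreqs = nodeFreqs, nodeSequences = seqs,
                 alignment = aln,
                 ogtTable = data.frame(),
                 params = list(nColumns = nColumns, alpha = alpha, k = k,
                               seed = seed))
  })
}

#' Simulate a full dataset with a latent temperature history
#'
#' Ties the pieces together: a Yule tree, a Brownian OGT trajectory, a
#' per-node residue composition realising each node's OGT under the
#' calibration line, and a non-stationary alignment evolved with those
#' compositions. The leaves' true OGTs are emitted as an OGT table, so the
#' whole pipeline (calibrate, reconstruct, predict) can be checked against
#' recorded truth.
#'
#' @param nLeaves,nColumns problem size.
#' @param rootOgt root temperature, degC.
#' @param sigma Brownian OGT step scale (degC per sqrt branch length).
#' @param meanBranchLength Yule mean branch length, substitutions/site.
#' @param calibration [CalibrationModel-class] defining the CvP-OGT line.
#' @param alpha,k discrete-gamma rate heterogeneity.
#' @param exchangeabilities "LG"/"WAG" or a custom symmetric matrix.
#' @param seed optional integer seed governing tree, trajectory and
#'   sequences.
#' @return A [SyntheticTruth-class].
#' @export
simulateDataset <- function(nLeaves = 32L, nColumns = 3000L, rootOgt = 95,
                            sigma = 8, meanBranchLength = 0.5,
                            calibration = defaultCalibration(),
                            alpha = 0.8, k = 4L,
                            exchangeabilities = "LG", seed = NULL) {
  .withSeed(seed, {
    tree <- simulateYuleTree(nLeaves, meanBranchLength)
    ogt <- simulateOgtTrajectory(tree, rootOgt, sigma)
    base <- .lgFreqs()
    nodeFreqs <- t(vapply(ogt, function(o)
      compositionForOgt(o, calibration, base), numeric(20L)))
    truth <- simulateAlignment(tree, nodeFreqs, nColumns,
                               exchangeabilities, alpha, k)
    truth@nodeOgt <- ogt
    n <- ape::Ntip(tree)
    truth@ogtTable <- data.frame(taxon = tree$tip.label,
                                 ogt_celsius = unname(ogt[seq_len(n)]),
                                 copy_id = "1", psychrophile = FALSE,
                                 stringsAsFactors = FALSE)
    truth@params <- c(truth@params,
                      list(rootOgt = rootOgt, sigma = sigma,
                           meanBranchLength = meanBranchLength,
                           datasetSeed = seed))
    truth
  })
}

## Integer residue counts of length L realising CvP x to the count grid:
## largest-remainder rounding of the target composition, then minimal
## class moves so that (n_charged - n_polar) = round(x L / 100).
.countsForCvp <- function(x, L, baseFreqs) {
  comp <- .compositionForCvp(x, baseFreqs)
  counts <- floor(comp * L)
  rem <- comp * L - counts
  short <- L - sum(counts)
  if (short > 0) {
    ord <- order(rem, decreasing = TRUE)
    counts[ord[seq_len(short)]] <- counts[ord[seq_len(short)]] + 1L
  }
  target <- round(x * L / 100)
  repeat {
    diff <- (sum(counts[.AA_CHARGED]) - sum(counts[.AA_POLAR])) - target
    if (diff == 0) break
    if (abs(diff) >= 2) {
      if (diff > 0) {  # move charged -> polar
        from <- .AA_CHARGED[which.max(counts[.AA_CHARGED])]
        to <- .AA_POLAR[which.max(counts[.AA_POLAR])]
      } else {
        from <- .AA_POLAR[which.max(counts[.AA_POLAR])]
        to <- .AA_CHARGED[which.max(counts[.AA_CHARGED])]
      }
    } else {          # odd residual: route one unit through "other"
      other <- setdiff(.AA, c(.AA_CHARGED, .AA_POLAR))
      if (diff > 0) {
        from <- .AA_CHARGED[which.max(counts[.AA_CHARGED])]
        to <- other[which.max(counts[other])]
      } else {
        from <- other[which.max(counts[other])]
        to <- .AA_CHARGED[which.max(counts[.AA_CHARGED])]
      }
    }
    if (counts[from] < 1L) stop("cannot realise CvP ", x, " with length ", L)
    counts[from] <- counts[from] - 1L
    counts[to] <- counts[to] + 1L
  }
  counts
}

#' Generate a synthetic calibration panel
#'
#' Emulates a panel of extant species with known OGTs whose CvP bias
#' follows a linear CvP-OGT law: an over-represented mesophile group at
#' 37 degC, optional psychrophiles (flagged, drawn off the line to mimic
#' their distinct adaptation), and the remaining species uniform over
#' \code{ogtRange}. Each species' target CvP is the true line plus
#' Normal(0, noiseSd) noise; its sequence realises that CvP to the nearest
#' value achievable with integer residue counts (granularity 100 /
#' seqLength percentage points; the exact targets are kept in the table's
#' \code{cvp} column, the realised values in \code{cvp_realized}).
#'
#' @param nSpecies total species count, >= 3.
#' @param ogtRange OGT range of the non-37, non-psychrophile species, degC.
#' @param noiseSd CvP noise around the line, percentage points.
#' @param nAt37 size of the 37 degC group.
#' @param nPsychrophiles number of flagged psychrophiles (OGT 5-15 degC).
#' @param trueSlope,trueIntercept the generating line.
#' @param seqLength emitted sequence length.
#' @param seed optional integer seed.
#' @return list with \code{table} (taxon, ogt_celsius, copy_id,
#'   psychrophile, cvp, cvp_realized), \code{alignment}
#'   ([ProteinAlignment-class] of the sequences) and \code{params}.
#' @export
makeCalibrationPanel <- function(nSpecies = 37L, ogtRange = c(45, 100),
                                 noiseSd = 1.5, nAt37 = 18L,
                                 nPsychrophiles = 2L, trueSlope = 6.7548,
                                 trueIntercept = 13.858, seqLength = 1000L,
                                 seed = NULL) {
  if (nSpecies < 3L) stop("nSpecies must be >= 3")
  nOther <- nSpecies - nAt37 - nPsychrophiles
  if (nOther < 1L) stop("nAt37 + nPsychrophiles must leave at least one species")
  .withSeed(seed, {
    ogt <- c(rep(37, nAt37),
             stats::runif(nOther, ogtRange[1L], ogtRange[2L]),
             stats::runif(nPsychrophiles, 5, 15))
    psy <- c(rep(FALSE, nAt37 + nOther), rep(TRUE, nPsychrophiles))
    cvp <- (ogt - trueIntercept) / trueSlope +
      stats::rnorm(nSpecies, 0, noiseSd)
    cvp[psy] <- cvp[psy] + 2.5          # psychrophiles sit off the line
    base <- .lgFreqs()
    seqs <- vapply(cvp, function(x) {
      counts <- .countsForCvp(x, seqLength, base)
      paste0(sample(rep(.AA, counts)), collapse = "")
    }, character(1L))
    taxa <- sprintf("sp%02d", seq_len(nSpecies))
    names(seqs) <- taxa
    aln <- proteinAlignment(seqs)
    table <- data.frame(taxon = taxa, ogt_celsius = ogt, copy_id = "1",
                        psychrophile = psy, cvp = cvp,
                        cvp_realized = unname(cvpBias(aln)),
                        stringsAsFactors = FALSE)
    list(table = table, alignment = aln,
         params = list(nSpecies = nSpecies, ogtRange = ogtRange,
                       noiseSd = noiseSd, nAt37 = nAt37,
                       nPsychrophiles = nPsychrophiles,
                       trueSlope = trueSlope, trueIntercept = trueIntercept,
                       seqLength = seqLength, seed = seed))
  })
}
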
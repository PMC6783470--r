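## Canonical residue order used throughout (PAML .dat convention).
.AA <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F","P","S","T","W","Y","V")
.AA_CHARGED <- c("R","K","D","E")
.AA_POLAR   <- c("Q","N","S","T")
.AA_AMBIG   <- c("X","B","Z")
.GAP        <- c("-",".")

#' Gapped protein multiple sequence alignment
#'
#' A validated container for an aligned set of protein sequences: unique
#' identifiers and a character matrix (one row per sequence, one column per
#' alignment position) over the 20 canonical residues, the gap character
#' \code{-}, and the ambiguity codes \code{X}, \code{B}, \code{Z}.
#'
#' @slot ids character vector of unique, non-empty sequence identifiers.
#' @slot chars character matrix of single upper-case characters; rownames are
#'   the ids.
#'
#' @seealso [readFastaAlignment()], [cvpBias()]
#' @export
setClass("ProteinAlignment", representation(ids = "character",
                                            chars = "matrix"))

setValidity("ProteinAlignment", function(object) {
  msg <- character()
  if (length(object@ids) == 0L)
    msg <- c(msg, "alignment must contain at least one sequence")
  if (anyDuplicated(object@ids))
    msg <- c(msg, "sequence ids must be unique")
  if (any(!nzchar(object@ids)))
    msg <- c(msg, "sequence ids must be non-empty")
  if (!is.character(object@chars))
    msg <- c(msg, "alignment matrix must be character")
  if (nrow(object@chars) != length(object@ids))
    msg <- c(msg, "one matrix row per id required")
  if (ncol(object@chars) < 1L)
    msg <- c(msg, "alignment must have at least one column")
  bad <- matrix(!(object@chars %in% c(.AA, .AA_AMBIG, "-")),
                nrow = nrow(object@chars))
  if (any(bad)) {
    w <- which(bad, arr.ind = TRUE)[1L, ]
    msg <- c(msg, sprintf("illegal character '%s' in sequence '%s' at column %d",
                          object@chars[w[1L], w[2L]], object@ids[w[1L]], w[2L]))
  }
  if (length(msg)) msg else TRUE
})

#' Linear CvP-to-OGT calibration model
#'
#' Coefficients of the line OGT = slope * CvP + intercept, with the CvP bias
#' expressed in percentage points and OGT in degrees Celsius, plus fit
#' diagnostics.
#'
#' @slot slope numeric(1), degC per CvP percentage point.
#' @slot intercept numeric(1), degC.
#' @slot rSquared numeric(1) in [0, 1]; squared Pearson correlation.
#' @slot nPoints integer(1); number of calibration points (0 for built-in
#'   models whose point set is not shipped).
#' @slot pValue numeric(1); two-sided t-test p-value of the slope
#'   (diagnostic only; NA when not fitted here).
#' @slot note character(1) provenance note.
#'
#' @seealso [fitCalibration()], [predictOgt()], [defaultCalibration()]
#' @export
setClass("CalibrationModel", representation(slope = "numeric",
                                            intercept = "numeric",
                                            rSquared = "numeric",
                                            nPoints = "integer",
                                            pValue = "numeric",
                                            note = "character"))

setValidity("CalibrationModel", function(object) {
  msg <- character()
  if (!is.finite(object@slope) || !is.finite(object@intercept))
    msg <- c(msg, "slope and intercept must be finite")
  if (!is.na(object@rSquared) &&
      (object@rSquared < 0 || object@rSquared > 1 + 1e-12))
    msg <- c(msg, "rSquared must lie in [0, 1]")
  if (object@nPoints < 0L)
    msg <- c(msg, "nPoints must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Reversible amino-acid substitution model with discrete-gamma rates
#'
#' An empirical exchangeability matrix combined with equilibrium frequencies
#' yields a time-reversible rate matrix Q, normalised to one expected
#' substitution per site at equilibrium. Among-site rate heterogeneity is a
#' k-category discrete gamma (equal category probabilities, category rates
#' are the means of the gamma quantile slices, averaging to 1).
#'
#' The eigendecomposition of the pi^{1/2}-symmetrised Q is precomputed so
#' transition matrices are cheap.
#'
#' @slot name model name, e.g. "LG" or "WAG".
#' @slot exchangeabilities symmetric 20 x 20 matrix, zero diagonal.
#' @slot freqs equilibrium frequencies, length 20, summing to 1.
#' @slot Q normalised rate matrix (rows sum to 0).
#' @slot alpha gamma shape (> 0).
#' @slot k number of rate categories (>= 1).
#' @slot rates the k category rates (mean 1).
#' @slot eig list with components values, left, right such that
#'   expm(Q t) = left \%*\% diag(exp(values t)) \%*\% right.
#'
#' @seealso [substitutionModel()], [transitionMatrix()], [discreteGammaRates()]
#' @export
setClass("SubstitutionModel", representation(name = "character",
                                             exchangeabilities = "matrix",
                                             freqs = "numeric",
                                             Q = "matrix",
                                             alpha = "numeric",
                                             k = "integer",
                                             rates = "numeric",
                                             eig = "list"))

setValidity("SubstitutionModel", function(object) {
  msg <- character()
  p <- object@freqs; Q <- object@Q
  if (length(p) != 20L || abs(sum(p) - 1) > 1e-12 || any(p <= 0))
    msg <- c(msg, "frequencies must be 20 positive values summing to 1")
  if (!isTRUE(all.equal(dim(Q), c(20L, 20L))))
    msg <- c(msg, "Q must be 20 x 20")
  else {
    if (max(abs(rowSums(Q))) > 1e-10)
      msg <- c(msg, "Q rows must sum to 0")
    off <- Q; diag(off) <- 0
    if (any(off < -1e-12))
      msg <- c(msg, "off-diagonal rates must be non-negative")
    db <- p * Q - t(p * Q)  # pi_i Q_ij symmetric under reversibility
    if (max(abs(db)) > 1e-10)
      msg <- c(msg, "model is not time-reversible (detailed balance violated)")
    if (abs(-sum(p * diag(Q)) - 1) > 1e-10)
      msg <- c(msg, "Q must be calibrated to one expected substitution per site")
  }
  if (object@alpha <= 0) msg <- c(msg, "alpha must be positive")
  if (object@k < 1L) msg <- c(msg, "k must be >= 1")
  if (any(object@rates <= 0) || abs(mean(object@rates) - 1) > 1e-12)
    msg <- c(msg, "category rates must be positive with mean 1")
  if (length(msg)) msg else TRUE
})

#' Per-node marginal ancestral state posteriors
#'
#' For every internal node of a rooted tree, the per-column posterior
#' distribution over the 20 residues, the maximum-a-posteriori (MAP) residue
#' per column (alphabetical tie-break) and its posterior probability.
#'
#' @slot nodeIds character vector of internal-node identifiers.
#' @slot profiles named list of (columns x 20) probability matrices, columns
#'   of the matrix named by residue in the model order.
#' @slot mapSequences named character vector of MAP ancestral sequences.
#' @slot mapPosteriors named list of per-column MAP posterior probabilities.
#' @slot logLikelihood total alignment log-likelihood (the posterior
#'   normaliser).
#'
#' @seealso [marginalAncestralProfiles()], [expectedCvp()]
#' @export
setClass("AncestralProfiles", representation(nodeIds = "character",
                                             profiles = "list",
                                             mapSequences = "character",
                                             mapPosteriors = "list",
                                             logLikelihood = "numeric"))

setValidity("AncestralProfiles", function(object) {
  msg <- character()
  if (length(object@profiles) != length(object@nodeIds) ||
      length(object@mapSequences) != length(object@nodeIds))
    msg <- c(msg, "profiles and MAP sequences must match nodeIds")
  for (pr in object@profiles) {
    if (max(abs(rowSums(pr) - 1)) > 1e-9) {
      msg <- c(msg, "each column distribution must sum to 1")
      break
    }
  }
  if (length(msg)) msg else TRUE
})

#' Ground truth of a synthetic dataset
#'
#' Everything the simulator knew: the rooted tree, true node OGTs, true
#' node equilibrium frequencies, the true (unobserved) ancestral sequences,
#' the emitted leaf alignment and OGT table, and the simulation parameters.
#'
#' @slot tree rooted \code{phylo}.
#' @slot nodeOgt named numeric of true OGTs for every node (degC).
#' @slot nodeFreqs node x 20 matrix of true equilibrium frequencies.
#' @slot nodeSequences named character of true sequences at every node.
#' @slot alignment [ProteinAlignment-class] of the leaf sequences.
#' @slot ogtTable data.frame OGT table for the leaves.
#' @slot params named list of simulation parameters (incl. seed).
#'
#' @seealso [simulateDataset()], [simulateAlignment()]
#' @export
setClass("SyntheticTruth", representation(tree = "ANY",
                                          nodeOgt = "numeric",
                                          nodeFreqs = "matrix",
                                          nodeSequences = "character",
                                          alignment = "ANY",
                                          ogtTable = "data.frame",
                                          params = "list"))

#' Result of the ancestral-OGT pipeline
#'
#' @slot tree rooted \code{phylo} used for reconstruction.
#' @slot annotations data.frame with one row per node: node id, leaf flag,
#'   MAP-sequence CvP, posterior-expected CvP, the two OGT predictions, and
#'   (for leaves) the tabled OGT when known.
#' @slot calibration the active [CalibrationModel-class].
#' @slot profiles the [AncestralProfiles-class] of the run.
#' @slot config named list of resolved pipeline settings.
#' @slot log character vector of timestamped stage messages.
#'
#' @seealso [runPipeline()], [summarizeCladeOgt()]
#' @export
setClass("OgtPipelineResult", representation(tree = "ANY",
                                             annotations = "data.frame",
                                             calibration = "ANY",
                                             profiles = "ANY",
                                             config = "list",
                                             log = "character"))
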
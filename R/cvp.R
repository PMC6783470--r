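#' Residue classes of the CvP statistic
#'
#' Charged residues are arginine, lysine, aspartate and glutamate; polar
#' (non-charged) residues are glutamine, asparagine, serine and threonine.
#' The remaining twelve canonical residues belong to neither class.
#'
#' @return list with components \code{charged} and \code{polar}.
#' @export
residueClasses <- function() list(charged = .AA_CHARGED, polar = .AA_POLAR)

#' Classify a single residue for the CvP statistic
#'
#' @param aa one of the 20 canonical amino-acid letters.
#' @return "charged", "polar", or "other".
#' @examples
#' classifyResidue("R")  # charged
#' classifyResidue("Q")  # polar
#' @export
classifyResidue <- function(aa) {
  if (length(aa) != 1L || !is.character(aa) || !(toupper(aa) %in% .AA))
    stop("not a canonical residue (gaps and ambiguity codes must be excluded by the caller): ",
         deparse(aa))
  aa <- toupper(aa)
  if (aa %in% .AA_CHARGED) "charged"
  else if (aa %in% .AA_POLAR) "polar"
  else "other"
}

#' CvP bias of a protein sequence
#'
#' The difference between the proportions of charged (R, K, D, E) and polar
#' non-charged (Q, N, S, T) residues, in percentage points:
#' \code{100 * (n_charged - n_polar) / n_counted}, where only canonical
#' residues are counted. Gaps and the ambiguity codes X/B/Z are excluded
#' from both numerator and denominator.
#'
#' @param sequence a sequence string (possibly gapped), a character vector
#'   of single residues, or a [ProteinAlignment-class] (one value per row).
#' @return CvP bias in percentage points, in [-100, 100].
#' @examples
#' cvpBias("RKDE")       # +100
#' cvpBias("RKDEQNST")   # 0
#' cvpBias("RRQG")       # +25
#' @export
cvpBias <- function(sequence) {
  if (methods::is(sequence, "ProteinAlignment")) {
    m <- alignmentMatrix(sequence)
    return(stats::setNames(
      vapply(seq_len(nrow(m)), function(i) .cvpChars(m[i, ]), numeric(1L)),
      alignmentIds(sequence)))
  }
  if (length(sequence) == 1L && nchar(sequence) > 1L)
    sequence <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  .cvpChars(toupper(sequence))
}

.cvpChars <- function(ch) {
  ch <- ch[!(ch %in% c(.GAP, .AA_AMBIG))]
  bad <- !(ch %in% .AA)
  if (any(bad)) stop("illegal residue in sequence: ", ch[bad][1L])
  n <- length(ch)
  if (n == 0L) stop("no canonical residues left after removing gaps/ambiguity codes")
  100 * (sum(ch %in% .AA_CHARGED) - sum(ch %in% .AA_POLAR)) / n
}

#' Posterior-expected CvP bias of an ancestral profile
#'
#' The CvP bias of a per-column residue distribution: 100 times the mean
#' over columns of P(charged) - P(polar). For a point-mass profile this
#' equals [cvpBias()] of the corresponding sequence.
#'
#' @param profile a (columns x 20) probability matrix with residue-named
#'   columns, or an [AncestralProfiles-class] (one value per node).
#' @return CvP bias in percentage points.
#' @export
expectedCvp <- function(profile) {
  if (methods::is(profile, "AncestralProfiles")) {
    return(stats::setNames(
      vapply(profile@profiles, expectedCvp, numeric(1L)),
      profile@nodeIds))
  }
  if (!is.matrix(profile) || ncol(profile) != 20L ||
      is.null(colnames(profile)) || !setequal(colnames(profile), .AA))
    stop("profile must be a (columns x 20) matrix with residue-named columns")
  rs <- rowSums(profile)
  if (any(abs(rs - 1) > 1e-9) || any(profile < -1e-12))
    stop("malformed distribution: each column must sum to 1 with non-negative mass")
  100 * mean(rowSums(profile[, .AA_CHARGED, drop = FALSE]) -
             rowSums(profile[, .AA_POLAR, drop = FALSE]))
}
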
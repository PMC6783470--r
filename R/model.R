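#' Discrete-gamma rate categories
#'
#' Equal-probability discretisation of a gamma(alpha, alpha) distribution
#' (mean 1): each category rate is the mean of its quantile slice, so rates
#' are nondecreasing and average exactly 1.
#'
#' @param alpha gamma shape, > 0.
#' @param k number of categories, >= 1.
#' @return numeric(k) of positive rates with mean 1.
#' @examples
#' discreteGammaRates(0.5, 4)
#' @export
discreteGammaRates <- function(alpha, k) {
  if (!is.finite(alpha) || alpha <= 0) stop("alpha must be positive")
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop("k must be an integer >= 1")
  if (k == 1L) return(1)
  q <- stats::qgamma(seq(0, 1, length.out = k + 1L), shape = alpha, rate = alpha)
  ## E[X; a<X<b] for X~Gamma(alpha, alpha) is the shape+1 cdf difference
  cum <- stats::pgamma(q, shape = alpha + 1, rate = alpha)
  r <- k * diff(cum)
  r / mean(r)   # remove tail-quadrature rounding so the mean is exactly 1
}

## Parse a PAML-format .dat file: 19 lower-triangle rows then frequencies.
.readPamlDat <- function(path) {
  nums <- scan(path, what = numeric(), quiet = TRUE)
  if (length(nums) != 190L + 20L)
    stop("malformed PAML dat file: ", path)
  R <- matrix(0, 20L, 20L, dimnames = list(.AA, .AA))
  pos <- 1L
  for (i in 2:20) {           # row-major lower triangle
    R[i, 1:(i - 1L)] <- nums[pos:(pos + i - 2L)]
    pos <- pos + i - 1L
  }
  R <- R + t(R)
  f <- nums[191:210]
  list(R = R, freqs = f / sum(f))
}

#' Alignment-empirical equilibrium frequencies ("+F")
#'
#' Observed residue frequencies with add-one smoothing over the counted
#' canonical residues (gaps and ambiguity codes ignored), so every residue
#' has positive frequency.
#'
#' @param alignment a [ProteinAlignment-class].
#' @return named numeric(20) summing to 1, in model residue order.
#' @export
empiricalFrequencies <- function(alignment) {
  ch <- alignmentMatrix(alignment)
  counts <- table(factor(ch[ch %in% .AA], levels = .AA)) + 1
  out <- as.numeric(counts) / sum(counts)
  names(out) <- .AA
  out
}

#' Build a reversible amino-acid substitution model
#'
#' Combines an empirical exchangeability matrix (LG or WAG, shipped as
#' PAML-format text tables; or a custom symmetric matrix) with equilibrium
#' frequencies into a rate matrix Q_ij = s_ij * pi_j, normalised to one
#' expected substitution per site, plus a k-category discrete-gamma rate
#' distribution.
#'
#' @param name "LG" or "WAG", or ignored when \code{exchangeabilities} is
#'   given.
#' @param frequencies \code{NULL} for the model's own frequencies, a
#'   [ProteinAlignment-class] for "+F" empirical frequencies, or a numeric
#'   vector of 20 frequencies in model residue order.
#' @param alpha gamma shape (default 1).
#' @param k number of rate categories (default 10).
#' @param exchangeabilities optional custom symmetric 20 x 20 matrix.
#' @return A [SubstitutionModel-class].
#' @examples
#' m <- substitutionModel("LG", alpha = 0.8, k = 4)
#' @export
substitutionModel <- function(name = c("LG", "WAG"), frequencies = NULL,
                              alpha = 1, k = 10L,
                              exchangeabilities = NULL) {
  if (is.null(exchangeabilities)) {
    name <- match.arg(name)
    dat <- .readPamlDat(system.file("extdata", paste0(name, ".dat"),
                                    package = "thermoasr", mustWork = TRUE))
    R <- dat$R
    freqsDefault <- dat$freqs
  } else {
    R <- exchangeabilities
    if (!isTRUE(all.equal(R, t(R)))) stop("exchangeabilities must be symmetric")
    if (is.character(name) && length(name) > 1L) name <- "custom"
    freqsDefault <- rep(1 / 20, 20L)
  }
  p <- if (is.null(frequencies)) freqsDefault
       else if (methods::is(frequencies, "ProteinAlignment"))
         empiricalFrequencies(frequencies)
       else as.numeric(frequencies)
  if (length(p) != 20L || any(p <= 0)) stop("need 20 positive frequencies")
  p <- p / sum(p)
  Q <- R * rep(p, each = 20L)            # Q_ij = s_ij pi_j
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  mu <- -sum(p * diag(Q))
  Q <- Q / mu
  dimnames(Q) <- list(.AA, .AA)
  ## symmetrise: A = D Q D^-1 with D = diag(sqrt(pi)) is symmetric
  sp <- sqrt(p)
  A <- Q * (sp %o% (1 / sp))
  A <- (A + t(A)) / 2
  eig <- eigen(A, symmetric = TRUE)
  methods::new("SubstitutionModel", name = name,
               exchangeabilities = R, freqs = stats::setNames(p, .AA), Q = Q,
               alpha = as.numeric(alpha), k = as.integer(k),
               rates = discreteGammaRates(alpha, k),
               eig = list(values = eig$values,
                          left = eig$vectors / sp,       # D^-1 U
                          right = t(eig$vectors * sp)))  # U' D
}

#' Return a model with a different gamma shape
#'
#' @param model a [SubstitutionModel-class].
#' @param alpha new gamma shape.
#' @return The model with updated alpha and category rates.
#' @export
setAlpha <- function(model, alpha) {
  model@alpha <- as.numeric(alpha)
  model@rates <- discreteGammaRates(alpha, model@k)
  methods::validObject(model)
  model
}

#' Transition probability matrix over an evolutionary distance
#'
#' exp(Q * distance) computed from the precomputed symmetrised
#' eigendecomposition. Tiny negative entries from round-off (>= -1e-12) are
#' clipped to zero.
#'
#' @param model a [SubstitutionModel-class].
#' @param distance branch length times rate category, >= 0, in
#'   substitutions/site.
#' @return 20 x 20 row-stochastic matrix.
#' @export
transitionMatrix <- function(model, distance) {
  if (!is.finite(distance) || distance < 0) stop("distance must be >= 0")
  if (distance == 0)                      # exact identity, no round-off
    return(diag(20L) + 0 * model@Q)
  P <- model@eig$left %*% (exp(model@eig$values * distance) * model@eig$right)
  P[P < 0] <- 0
  dimnames(P) <- list(.AA, .AA)
  P
}
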
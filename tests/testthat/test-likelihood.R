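uniformModel <- function(k = 1L, alpha = 1) {
  ex <- matrix(1, 20, 20); diag(ex) <- 0
  substitutionModel(exchangeabilities = ex, frequencies = rep(1 / 20, 20),
                    alpha = alpha, k = k, name = "uniform")
}

test_that("zero-distance degeneracies give the closed-form likelihood", {
  tr <- readNewick(text = "(A:0,B:0);")
  m <- uniformModel()
  aln <- proteinAlignment(c(A = "R", B = "R"))
  expect_equal(treeLogLikelihood(tr, aln, m), log(1 / 20), tolerance = 1e-12)
  aln2 <- proteinAlignment(c(A = "R", B = "K"))
  expect_warning(ll <- treeLogLikelihood(tr, aln2, m), "impossible")
  expect_identical(ll, -Inf)
})

test_that("pruning likelihood equals exhaustive enumeration on 4-leaf instances", {
  set.seed(5)
  for (rep in 1:3) {
    tr <- ape::rtree(4)
    tr$edge.length <- stats::runif(nrow(tr$edge), 0.05, 1.2)
    aln <- randomAlignment(tr$tip.label, 3L, seed = 100 + rep)
    m <- substitutionModel("LG", alpha = 0.6, k = 2)
    oracle <- enumOracle(tr, aln, m)
    expect_equal(treeLogLikelihood(tr, aln, m), oracle$logLik,
                 tolerance = 1e-10)
  }
})

test_that("likelihood matches phangorn on a larger seeded instance", {
  skip_if_not_installed("phangorn")
  set.seed(21)
  tr <- ape::rtree(8)
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.05, 0.8)
  aln <- randomAlignment(tr$tip.label, 120L, seed = 22)
  m <- substitutionModel("LG", frequencies = aln, alpha = 0.7, k = 4)
  pd <- phangorn::phyDat(t(vapply(sequenceStrings(aln),
                                  function(s) strsplit(s, "")[[1]],
                                  character(nColumns(aln)))), type = "AA")
  fit <- phangorn::pml(tr, pd, model = "LG", k = 4, shape = 0.7,
                       bf = equilibriumFreqs(m))
  expect_equal(treeLogLikelihood(tr, aln, m), fit$logLik, tolerance = 1e-8)
})

test_that("likelihood is invariant to re-rooting (pulley principle)", {
  skip_if_not_installed("phytools")
  set.seed(31)
  tr <- ape::rtree(8)
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.05, 0.8)
  truth <- stationaryAlignment(tr, substitutionModel("LG", alpha = 0.9, k = 2),
                               60L, seed = 32)
  aln <- truth@alignment
  m <- substitutionModel("LG", alpha = 0.9, k = 2)
  ref <- treeLogLikelihood(tr, aln, m)
  for (node in c(3L, 7L, ape::Ntip(tr) + 3L)) {
    re <- phytools::reroot(tr, node,
                           position = 0.3 * tr$edge.length[
                             which(tr$edge[, 2] == node)])
    expect_equal(treeLogLikelihood(re, aln, m), ref, tolerance = 1e-8)
  }
})

test_that("gamma shape is recovered from simulated data and flags boundaries", {
  tr <- simulateYuleTree(16, 0.3, seed = 41)
  m <- substitutionModel("LG", alpha = 0.7, k = 4)
  truth <- stationaryAlignment(tr, m, 2000L, seed = 42)
  fit <- estimateAlpha(tr, truth@alignment, substitutionModel("LG", alpha = 1,
                                                              k = 4))
  expect_lt(abs(fit$alpha - 0.7), 0.2)
  expect_false(fit$boundary)
  ## monotonicity: the fit is no worse than alpha = 1
  ll1 <- treeLogLikelihood(tr, truth@alignment,
                           substitutionModel("LG", alpha = 1, k = 4))
  expect_gte(fit$logLik, ll1)
  ## near-homogeneous rates push the estimate to the upper boundary
  mflat <- substitutionModel("LG", alpha = 50, k = 4)
  flat <- stationaryAlignment(tr, substitutionModel("LG", alpha = 1, k = 1),
                              400L, seed = 43)
  expect_warning(bfit <- estimateAlpha(tr, flat@alignment, mflat), "boundary")
  expect_true(bfit$boundary)
})

test_that("branch-length optimisation improves likelihood and recovers truth", {
  tr <- simulateYuleTree(6, 0.3, seed = 51)
  tr$edge.length <- pmin(pmax(tr$edge.length, 0.05), 1)
  m <- substitutionModel("LG", alpha = 1, k = 1)
  truth <- stationaryAlignment(tr, m, 2500L, seed = 52)
  start <- tr
  start$edge.length <- rep(0.3, nrow(tr$edge))
  opt <- optimizeBranchLengths(start, truth@alignment, m)
  expect_gte(opt$logLik, treeLogLikelihood(start, truth@alignment, m))
  rel <- abs(opt$tree$edge.length - tr$edge.length) / tr$edge.length
  expect_lt(stats::median(rel), 0.15)
  expect_true(all(rel < 0.35))
  ## already-optimal lengths are a fixed point
  again <- optimizeBranchLengths(opt$tree, truth@alignment, m)
  expect_lt(max(abs(again$tree$edge.length - opt$tree$edge.length)), 1e-3)
})

test_that("a zero-length branch between identical data stays at zero", {
  tr <- readNewick(text = "((A:0,B:0):0.3,(C:0.2,D:0.2):0.3);")
  aln <- proteinAlignment(c(A = "RNDCQE", B = "RNDCQE",
                            C = "KNDWQE", D = "KNDCYE"))
  m <- substitutionModel("LG", alpha = 1, k = 1)
  opt <- optimizeBranchLengths(tr, aln, m)
  e <- which(opt$tree$edge[, 2] == match("A", opt$tree$tip.label))
  expect_identical(opt$tree$edge.length[e], 0)
})
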
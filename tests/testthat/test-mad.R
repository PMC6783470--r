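test_that("pairwise leaf distances are path sums with metric properties", {
  tr <- readNewick(text = "(A:1,B:2,C:3);")
  D <- pairwiseLeafDistances(tr)
  expect_equal(D["A", "B"], 3)
  expect_equal(D["A", "C"], 4)
  expect_equal(D["B", "C"], 5)
  expect_equal(diag(D), c(A = 0, B = 0, C = 0))
  set.seed(91)
  tr2 <- ape::rtree(10)
  D2 <- pairwiseLeafDistances(tr2)
  expect_equal(D2, t(D2))
  for (i in 1:10) {
    abc <- sample(10, 3)
    expect_lte(D2[abc[1], abc[2]],
               D2[abc[1], abc[3]] + D2[abc[3], abc[2]] + 1e-12)
  }
  star <- readNewick(text = "(A:0,B:0,C:0);")
  expect_true(all(pairwiseLeafDistances(star) == 0))
})

test_that("the central branch of an ultrametric tree scores a midpoint root with zero spanning deviation", {
  tr <- readNewick(text = "((A:1,B:1):1,(C:1,D:1):1);")
  ut <- ape::unroot(tr)
  e <- which(ut$edge.length == 2)  # the central branch after unrooting
  sc <- scoreRootBranch(ut, e)
  expect_equal(sc$x, 1, tolerance = 1e-12)        # midpoint of the branch
  ## same-side pairs (siblings) also sit clocklike here: total score 0
  expect_equal(sc$score, 0, tolerance = 1e-12)
})

test_that("closed-form branch position matches dense grid search", {
  tr <- madFixtureTree()
  for (e in seq_len(nrow(tr$edge))) {
    sc <- scoreRootBranch(tr, e)
    gr <- gridMadScore(tr, e)
    ## x within one grid step of the grid argmin, scores agree to 1e-6,
    ## and the closed form is never worse than the best grid point
    expect_lt(abs(sc$x - gr$x), tr$edge.length[e] / 1e4 + 1e-12)
    expect_lt(abs(sc$score - gr$score), 1e-6)
    expect_lte(sc$score, gr$score + 1e-12)
    expect_gte(sc$x, 0)
    expect_lte(sc$x, tr$edge.length[e])
  }
})

test_that("clamped optima stay finite and no better than the unclamped minimum", {
  ## a pendant branch whose optimum lies at an endpoint
  tr <- madFixtureTree()
  scores <- vapply(seq_len(nrow(tr$edge)), function(e)
    scoreRootBranch(tr, e)$score, numeric(1))
  xs <- vapply(seq_len(nrow(tr$edge)), function(e)
    scoreRootBranch(tr, e)$x, numeric(1))
  clamped <- which(xs == 0 | xs == tr$edge.length)
  expect_gt(length(clamped), 0)
  expect_true(all(is.finite(scores)))
})

test_that("MAD rooting picks the grid-search branch and preserves the tree", {
  tr <- madFixtureTree()
  res <- madRoot(tr)
  gridBest <- which.min(vapply(seq_len(nrow(tr$edge)), function(e)
    gridMadScore(tr, e)$score, numeric(1)))
  expect_equal(res$candidates$branch[1], gridBest)
  expect_equal(sum(res$tree$edge.length), sum(tr$edge.length),
               tolerance = 1e-10)
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(res$tree), tr)), 0)
  expect_true(ape::is.rooted(res$tree))
  expect_gt(res$ambiguity, 0)
  expect_lte(res$ambiguity, 1)
  expect_equal(res$candidates$rank, seq_len(nrow(res$candidates)))
})

test_that("MAD equals midpoint rooting on ultrametric trees", {
  skip_if_not_installed("phangorn")
  set.seed(101)
  for (rep in 1:3) {
    tr <- ape::compute.brlen(ape::rtree(7), method = "Grafen")
    ut <- ape::unroot(tr)
    mad <- madRoot(ut)$tree
    mid <- phangorn::midpoint(ut)
    ## identical root bipartition
    rootSides <- function(t) {
      n <- ape::Ntip(t)
      kids <- t$edge[t$edge[, 1] == n + 1L, 2]
      sides <- lapply(kids, function(k)
        sort(if (k <= n) t$tip.label[k]
             else ape::extract.clade(t, k)$tip.label))
      sort(vapply(sides, paste, character(1), collapse = ","))
    }
    expect_equal(rootSides(mad), rootSides(mid))
    d1 <- ape::dist.nodes(mad)[ape::Ntip(mad) + 1, seq_len(ape::Ntip(mad))]
    expect_equal(max(d1), min(d1), tolerance = 1e-9)  # root equidistant
  }
})

test_that("scores are invariant under uniform branch scaling and relabeling", {
  tr <- madFixtureTree()
  res <- madRoot(tr)
  sc <- tr; sc$edge.length <- sc$edge.length * 17.3
  res2 <- madRoot(sc)
  expect_equal(res2$candidates$score, res$candidates$score, tolerance = 1e-12)
  expect_equal(res2$candidates$branch, res$candidates$branch)
  ## relabeled isomorphic tree roots isomorphically
  rl <- tr; rl$tip.label <- paste0("x_", tr$tip.label)
  res3 <- madRoot(rl)
  expect_equal(res3$candidates$score, res$candidates$score, tolerance = 1e-12)
  firstRootClade <- function(t) {
    n <- ape::Ntip(t)
    k <- t$edge[t$edge[, 1] == n + 1L, 2][1]
    sort(if (k <= n) t$tip.label[k] else ape::extract.clade(t, k)$tip.label)
  }
  left <- firstRootClade(res$tree)
  left3 <- sort(sub("x_", "", firstRootClade(res3$tree)))
  expect_true(identical(left, left3) ||
              identical(left, sort(setdiff(tr$tip.label, left3))))
})

test_that("degenerate inputs are rejected with names", {
  expect_error(madRoot(readNewick(text = "(A:1,B:1);")), "3 leaves")
  dup <- readNewick(text = "((A:0,B:0):1,C:1,D:1);")
  expect_error(madRoot(dup), "A / B|B / A")
})
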
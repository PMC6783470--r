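test_that("Yule trees have the right shape and are seed-deterministic", {
  tr3 <- simulateYuleTree(3, 0.2, seed = 1)
  expect_equal(ape::Ntip(tr3), 3L)
  expect_equal(tr3$Nnode, 2L)            # root split plus one further split
  expect_true(ape::is.rooted(tr3))
  tr <- simulateYuleTree(50, 0.2, seed = 7)
  expect_equal(nrow(tr$edge), 2L * 50L - 2L)
  expect_identical(ape::write.tree(tr),
                   ape::write.tree(simulateYuleTree(50, 0.2, seed = 7)))
  expect_false(identical(ape::write.tree(tr),
                         ape::write.tree(simulateYuleTree(50, 0.2, seed = 8))))
  expect_error(simulateYuleTree(2, 0.2), ">= 3")
})

test_that("OGT trajectories diffuse with the requested variance and clamp", {
  tr <- simulateYuleTree(8, 0.3, seed = 2)
  flat <- simulateOgtTrajectory(tr, 70, 0, seed = 3)
  expect_true(all(flat == 70))
  hot <- simulateOgtTrajectory(tr, 108, 30, seed = 4)
  expect_lte(max(hot), 110)
  expect_gte(min(hot), 5)
  ## Monte-Carlo variance on a single branch of length 1
  chain <- readNewick(text = "(A:1,B:1);")
  steps <- vapply(1:1000, function(s)
    simulateOgtTrajectory(chain, 60, 4, seed = 1000 + s)[["A"]] - 60,
    numeric(1))
  expect_lt(abs(stats::var(steps) - 16) / 16, 0.10)
})

test_that("compositionForOgt hits its target exactly and reports feasibility", {
  hua <- defaultCalibration()
  base <- equilibriumFreqs(substitutionModel("LG", k = 1))
  ## fixed point: the base composition's own OGT maps to itself
  ogt0 <- predictOgt(hua, 100 * (sum(base[c("R","K","D","E")]) -
                                 sum(base[c("Q","N","S","T")])))
  expect_equal(compositionForOgt(ogt0, hua, base), base, tolerance = 1e-12)
  for (ogt in c(10, 37, 63, 82, 93, 100)) {
    p <- compositionForOgt(ogt, hua, base)
    expect_equal(sum(p), 1, tolerance = 1e-12)
    x <- 100 * (sum(p[c("R","K","D","E")]) - sum(p[c("Q","N","S","T")]))
    expect_equal(x, (ogt - 13.858) / 6.7548, tolerance = 1e-10)
    ## round trip: predicted OGT of the built composition is the target
    expect_equal(predictOgt(hua, x), ogt, tolerance = 1e-9)
  }
  ## hand inversion of the default line at 100 degC
  p100 <- compositionForOgt(100, hua, base)
  x100 <- 100 * (sum(p100[c("R","K","D","E")]) - sum(p100[c("Q","N","S","T")]))
  expect_equal(x100, (100 - 13.858) / 6.7548, tolerance = 1e-10)
  expect_equal(x100, 12.75274, tolerance = 1e-5)
  expect_error(compositionForOgt(1e4, hua, base), "feasible OGT interval")
})

test_that("alignment simulation respects degenerate and stationary limits", {
  tr <- readNewick(text = "((A:0,B:0):0,C:0);")   # rooted, all lengths 0
  base <- equilibriumFreqs(substitutionModel("LG", k = 1))
  nf <- matrix(base, ape::Ntip(tr) + tr$Nnode, 20, byrow = TRUE)
  truth <- simulateAlignment(tr, nf, 200L, seed = 5)
  ss <- sequenceStrings(truth@alignment)
  expect_true(all(ss == ss[1]))          # zero lengths: everyone is the root
  ## long branch converges to the child equilibrium composition
  tr2 <- readNewick(text = "(A:5,B:5);")
  hot <- compositionForOgt(95, defaultCalibration(), base)
  nf2 <- rbind(hot, base, base)          # node order: A=1, B=2, root=3
  truth2 <- simulateAlignment(tr2, nf2, 10000L,
                              exchangeabilities = "LG", alpha = 1, k = 1,
                              seed = 6)
  sA <- strsplit(sequenceStrings(truth2@alignment)[["A"]], "")[[1]]
  obs <- table(factor(sA, levels = names(base))) / length(sA)
  for (cls in list(c("R","K","D","E"), c("Q","N","S","T"))) {
    expect_lt(abs(sum(obs[cls]) - sum(hot[cls])), 0.01)
  }
  ## seed determinism
  t1 <- simulateAlignment(tr2, nf2, 50L, seed = 9)
  t2 <- simulateAlignment(tr2, nf2, 50L, seed = 9)
  expect_identical(sequenceStrings(t1@alignment),
                   sequenceStrings(t2@alignment))
})

test_that("calibration panels have the documented structure", {
  pan <- makeCalibrationPanel(nSpecies = 37, nAt37 = 18, nPsychrophiles = 2,
                              noiseSd = 1.5, seed = 10)
  expect_equal(nrow(pan$table), 37L)
  expect_equal(sum(pan$table$ogt_celsius == 37), 18L)
  expect_equal(sum(pan$table$psychrophile), 2L)
  expect_true(all(pan$table$ogt_celsius[pan$table$psychrophile] < 20))
  ## collapse arithmetic: an n-at-37 group becomes one point
  pan0 <- makeCalibrationPanel(nSpecies = 37, nAt37 = 18, nPsychrophiles = 0,
                               seed = 11)
  pts <- buildCalibrationPoints(pan0$table,
                                pan0$table[, c("taxon", "copy_id", "cvp")])
  expect_equal(nrow(pts), 37L - 18L + 1L)
  ## sequences realise the target CvP to the count grid
  expect_lt(max(abs(pan$table$cvp - pan$table$cvp_realized)),
            50 / pan$params$seqLength + 1e-9)
  ## determinism
  pan2 <- makeCalibrationPanel(nSpecies = 37, nAt37 = 18, nPsychrophiles = 2,
                               noiseSd = 1.5, seed = 10)
  expect_identical(pan$table, pan2$table)
  expect_identical(sequenceStrings(pan$alignment),
                   sequenceStrings(pan2$alignment))
})

test_that("noise-free panels put every point on the generating line", {
  pan <- makeCalibrationPanel(nSpecies = 25, nAt37 = 10, nPsychrophiles = 2,
                              noiseSd = 0, seed = 12)
  keep <- !pan$table$psychrophile
  expect_equal(pan$table$ogt_celsius[keep],
               6.7548 * pan$table$cvp[keep] + 13.858, tolerance = 1e-9)
  ## psychrophiles sit off the line, so excluding them changes the slope
  ptsEx <- buildCalibrationPoints(pan$table,
                                  pan$table[, c("taxon", "copy_id", "cvp")])
  ptsIn <- buildCalibrationPoints(pan$table,
                                  pan$table[, c("taxon", "copy_id", "cvp")],
                                  excludePsychrophiles = FALSE)
  expect_false(isTRUE(all.equal(modelSlope(fitCalibration(ptsEx)),
                                modelSlope(fitCalibration(ptsIn)))))
})

test_that("simulateDataset records a complete, internally consistent truth", {
  truth <- simulateDataset(nLeaves = 8, nColumns = 120, seed = 13)
  tr <- truth@tree
  expect_equal(length(truth@nodeOgt), ape::Ntip(tr) + tr$Nnode)
  expect_equal(truth@nodeOgt[[treeNodeIds(tr)[ape::Ntip(tr) + 1]]], 95)
  expect_equal(unname(rowSums(truth@nodeFreqs)),
               rep(1, nrow(truth@nodeFreqs)), tolerance = 1e-12)
  expect_equal(truth@ogtTable$ogt_celsius,
               unname(truth@nodeOgt[seq_len(ape::Ntip(tr))]))
  ## node frequency truth matches each node's OGT through the line
  for (i in seq_len(nrow(truth@nodeFreqs))) {
    x <- 100 * (sum(truth@nodeFreqs[i, c(2, 12, 4, 7)]) -
                sum(truth@nodeFreqs[i, c(6, 3, 16, 17)]))
    expect_equal(predictOgt(defaultCalibration(), x),
                 unname(truth@nodeOgt[i]), tolerance = 1e-9)
  }
  truth2 <- simulateDataset(nLeaves = 8, nColumns = 120, seed = 13)
  expect_identical(sequenceStrings(truth@alignment),
                   sequenceStrings(truth2@alignment))
})
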
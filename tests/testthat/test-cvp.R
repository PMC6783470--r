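test_that("residue classification follows the charged/polar definition", {
  expect_equal(classifyResidue("R"), "charged")
  expect_equal(classifyResidue("Q"), "polar")
  expect_equal(classifyResidue("G"), "other")
  expect_setequal(residueClasses()$charged, c("R", "K", "D", "E"))
  expect_setequal(residueClasses()$polar, c("Q", "N", "S", "T"))
  expect_error(classifyResidue("-"), "canonical")
  expect_error(classifyResidue("X"), "canonical")
})

test_that("cvpBias counts canonical residues only", {
  expect_equal(cvpBias("RKDE"), 100)
  expect_equal(cvpBias("RKDEQNST"), 0)
  expect_equal(cvpBias("RRQG"), 25)      # (2 - 1) / 4 * 100
  expect_equal(cvpBias("R-K-X"), 100)    # gaps and X leave denominator
  expect_error(cvpBias("--XX"), "no canonical residues")
  expect_error(cvpBias("RKJE"), "illegal")
})

test_that("cvpBias is invariant to gaps and permutation, additive under concatenation", {
  set.seed(7)
  for (i in 1:20) {
    s <- paste0(sample(aaLetters, sample(10:60, 1), TRUE), collapse = "")
    ch <- strsplit(s, "")[[1]]
    gapped <- paste0(sample(c(ch, rep("-", 13))), collapse = "")
    expect_equal(cvpBias(gapped), cvpBias(s), tolerance = 1e-12)
    expect_equal(cvpBias(paste0(rev(ch), collapse = "")), cvpBias(s))
    s2 <- paste0(sample(aaLetters, sample(5:40, 1), TRUE), collapse = "")
    n1 <- nchar(s); n2 <- nchar(s2)
    expect_equal(cvpBias(paste0(s, s2)),
                 (n1 * cvpBias(s) + n2 * cvpBias(s2)) / (n1 + n2),
                 tolerance = 1e-12)
  }
})

test_that("expectedCvp agrees with cvpBias on point masses and hand expectations", {
  pm <- function(seq) {
    ch <- strsplit(seq, "")[[1]]
    p <- matrix(0, length(ch), 20L, dimnames = list(NULL, aaLetters))
    p[cbind(seq_along(ch), match(ch, aaLetters))] <- 1
    p
  }
  expect_equal(expectedCvp(pm("RKDE")), 100)
  expect_equal(expectedCvp(pm("RKDE")), cvpBias("RKDE"))
  unif <- matrix(1 / 20, 3L, 20L, dimnames = list(NULL, aaLetters))
  expect_equal(expectedCvp(unif), 0)
  ## col1 point mass R, col2 half Q half G:
  ## mean of (1 - 0) and (0 - 0.5) is 0.25 -> 25 percentage points
  two <- pm("RG"); two[2, ] <- 0; two[2, "Q"] <- 0.5; two[2, "G"] <- 0.5
  expect_equal(expectedCvp(two), 25)
  bad <- unif; bad[1, 1] <- 0.9
  expect_error(expectedCvp(bad), "malformed")
})

test_that("calibration points apply psychrophile exclusion, copy duplication and the 37-degree collapse", {
  rec <- data.frame(taxon = c("A", "B", "C"), ogt_celsius = c(37, 37, 80))
  pts <- buildCalibrationPoints(rec, c(A = 4, B = 6, C = 10))
  expect_equal(pts$cvp, c(5, 10))        # mean of the 37-degree group
  expect_equal(pts$ogt, c(37, 80))
  expect_equal(pts$n_sources, c(2L, 1L))

  rec <- data.frame(taxon = c("A", "B"), ogt_celsius = c(55, 10),
                    psychrophile = c(FALSE, TRUE))
  pts <- buildCalibrationPoints(rec, c(A = 7, B = 9))
  expect_equal(nrow(pts), 1L)
  expect_equal(pts$sources, "A:1")
  pts2 <- buildCalibrationPoints(rec, c(A = 7, B = 9),
                                 excludePsychrophiles = FALSE)
  expect_equal(nrow(pts2), 2L)

  rec <- data.frame(taxon = "S", ogt_celsius = 65, copy_id = c("c1", "c2"))
  cvps <- data.frame(taxon = "S", copy_id = c("c1", "c2"), cvp = c(8, 9))
  pts <- buildCalibrationPoints(rec, cvps)
  expect_equal(pts$cvp, c(8, 9))         # two copies, same OGT, two points
  expect_equal(pts$ogt, c(65, 65))

  expect_error(buildCalibrationPoints(rec, cvps[1, ]), "no CvP")
})

test_that("calibration points are order-independent and support duplicate-OGT collapsing", {
  rec <- data.frame(taxon = letters[1:6],
                    ogt_celsius = c(37, 37, 55, 55, 80, 90))
  cvps <- stats::setNames(c(3, 5, 6, 8, 10, 11), letters[1:6])
  a <- buildCalibrationPoints(rec, cvps)
  perm <- sample(6)
  b <- buildCalibrationPoints(rec[perm, ], cvps[perm])
  expect_equal(a, b)
  dup <- buildCalibrationPoints(rec, cvps, collapse = "duplicates")
  expect_equal(dup$ogt, c(37, 55, 80, 90))
  expect_equal(dup$cvp, c(4, 7, 10, 11))
})

test_that("fitCalibration recovers exact lines and rejects degenerate input", {
  pts <- data.frame(cvp = 1:5, ogt = 2 * (1:5) + 5)
  m <- fitCalibration(pts)
  expect_equal(modelSlope(m), 2, tolerance = 1e-12)
  expect_equal(modelIntercept(m), 5, tolerance = 1e-12)
  expect_equal(rSquared(m), 1, tolerance = 1e-12)
  m2 <- fitCalibration(data.frame(cvp = c(5, 10, 7.5),
                                  ogt = c(37, 80, 58.5)))
  expect_equal(modelSlope(m2), 8.6, tolerance = 1e-10)
  expect_equal(modelIntercept(m2), -6, tolerance = 1e-9)
  expect_equal(rSquared(m2), 1, tolerance = 1e-12)
  expect_error(fitCalibration(data.frame(cvp = c(1, 1, 1), ogt = 1:3)),
               "singular")
  expect_error(fitCalibration(data.frame(cvp = 1:2, ogt = 1:2)),
               "insufficient")
})

test_that("noise-free OLS recovery and the centroid property hold on generated points", {
  set.seed(11)
  for (i in 1:10) {
    a <- stats::runif(1, -5, 8); b <- stats::runif(1, -30, 50)
    x <- stats::runif(sample(5:40, 1), -10, 15)
    m <- fitCalibration(data.frame(cvp = x, ogt = a * x + b))
    expect_equal(modelSlope(m), a, tolerance = 1e-10)
    expect_equal(modelIntercept(m), b, tolerance = 1e-10)
    expect_equal(rSquared(m), 1, tolerance = 1e-9)
    y <- a * x + b + stats::rnorm(length(x), 0, 3)
    mn <- fitCalibration(data.frame(cvp = x, ogt = y))
    expect_equal(predictOgt(mn, mean(x)), mean(y), tolerance = 1e-9)
  }
})

test_that("predictOgt applies the affine model, including the built-in default", {
  hua <- defaultCalibration("hua2019")
  expect_equal(predictOgt(hua, 0), 13.858)
  expect_equal(predictOgt(hua, 10), 81.406)
  flat <- calibrationModel(0, 50)
  expect_equal(predictOgt(flat, c(-40, 0, 99)), c(50, 50, 50))
  expect_error(predictOgt(hua, NaN), "non-finite")
})
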
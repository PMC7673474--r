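test_that("z-scoring standardises every subject-feature slice", {
  set.seed(1)
  arr <- array(rnorm(5 * 10 * 4), dim = c(5, 10, 4))
  tab <- makeTable(arr)
  z <- zscoreFeatures(tab)
  v <- featureValues(z)
  for (s in 1:5) for (f in 1:4) {
    expect_lt(abs(mean(v[s, , f])), 1e-12)
    expect_equal(sd(v[s, , f]), 1, tolerance = 1e-12)
  }
  # affine invariance: a*x + b (a > 0) gives identical z-scores
  arr2 <- arr
  arr2[, , 2] <- 3.7 * arr[, , 2] - 11
  expect_equal(featureValues(zscoreFeatures(makeTable(arr2))), v,
               tolerance = 1e-12)
  # constant slice is a hard error naming the slice
  arr3 <- arr
  arr3[2, , 3] <- 5
  expect_error(zscoreFeatures(makeTable(arr3)), "s02.*F3")
})

test_that("subject MSN entries follow the Pearson profile correlation", {
  a <- c(0, 1, 2, 3, 4, 5, 6, 7)
  b <- c(0, 1, 2, 3, 4, 5, 7, 6)
  # independent covariance-formula oracle
  oracle <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(oracle, 41 / 42)
  arr <- array(0, dim = c(1, 4, 8))
  arr[1, 1, ] <- a
  arr[1, 2, ] <- b
  arr[1, 3, ] <- a                      # identical profile
  arr[1, 4, ] <- -(a - mean(a))         # negated centered profile
  m <- subjectMSN(makeTable(arr, zscored = TRUE), 1)
  v <- simValues(m)
  expect_equal(v[1, 2], 41 / 42, tolerance = 1e-12)
  expect_equal(v[1, 3], 1, tolerance = 1e-12)
  expect_equal(v[1, 4], -1, tolerance = 1e-12)
  expect_equal(diag(v), rep(1, 4), ignore_attr = TRUE)

  arrBad <- arr
  arrBad[1, 3, ] <- 2
  expect_error(subjectMSN(makeTable(arrBad, zscored = TRUE), 1),
               "parcel 3")
})

test_that("group MSN is the elementwise mean of subject matrices", {
  set.seed(2)
  mats <- replicate(5, blockMatrix(c(3, 3), noise = 0.2), simplify = FALSE)
  gm <- groupMSN(mats)
  oracle <- Reduce(`+`, lapply(mats, function(m) m@values)) / 5
  diag(oracle) <- 1
  expect_equal(gm@values, oracle, tolerance = 1e-14)
  expect_equal(matrixKind(gm), "group_msn")
  # idempotence and cancellation
  expect_equal(groupMSN(mats[c(1, 1)])@values, mats[[1]]@values,
               tolerance = 1e-14)
  plus <- blockMatrix(c(2, 2), within = 0.4, between = 0.4)
  minus <- blockMatrix(c(2, 2), within = -0.4, between = -0.4)
  z <- groupMSN(list(plus, minus))@values
  expect_equal(z[upper.tri(z)], rep(0, 6), tolerance = 1e-14)
  # mismatched orderings rejected
  other <- new("SimilarityMatrix", parcels = c(2L, 1L, 3L, 4L, 5L, 6L),
               values = mats[[1]]@values, kind = "subject_msn")
  expect_error(groupMSN(list(mats[[1]], other)), "mismatch")
})

test_that("leave-one-out respects redundancy and its contract", {
  set.seed(3)
  arr <- array(rnorm(6 * 8 * 4), dim = c(6, 8, 4))
  arr8 <- array(0, dim = c(6, 8, 5),
                dimnames = list(sprintf("s%02d", 1:6), 1:8,
                                c("A", "B", "C", "D", "Ddup")))
  arr8[, , 1:4] <- arr
  arr8[, , 5] <- arr[, , 4]             # exact duplicate of D
  tab <- new("FeatureTable", values = arr8, zscored = FALSE)
  # dropping the duplicate equals the pipeline on the deduplicated set
  dedup <- buildGroupMSN(makeTable(arr))
  expect_equal(leaveOneOutGroupMSN(tab, "Ddup")@values, dedup@values,
               tolerance = 1e-12)
  # contract: one matrix per excluded feature, symmetric, unit diagonal
  for (f in c("A", "B", "C")) {
    m <- leaveOneOutGroupMSN(tab, f)
    expect_s4_class(m, "SimilarityMatrix")
    expect_equal(diag(m@values), rep(1, 8), ignore_attr = TRUE)
  }
  expect_error(leaveOneOutGroupMSN(tab, "nope"), "unknown feature")
  tab4 <- makeTable(arr)
  expect_error(leaveOneOutGroupMSN(makeTable(arr[, , 1:3, drop = FALSE]),
                                   "F1"), "3 features")
})

test_that("single-feature SCN correlates parcels across subjects", {
  set.seed(4)
  x <- rnorm(20)
  arr <- array(rnorm(20 * 4 * 3), dim = c(20, 4, 3))
  arr[, 1, 1] <- x
  arr[, 2, 1] <- 2 * x + 5              # perfectly correlated
  arr[, 3, 1] <- -x + 3                 # perfectly anti-correlated
  scn <- singleFeatureSCN(makeTable(arr), "F1")
  v <- simValues(scn)
  expect_equal(v[1, 2], 1, tolerance = 1e-12)
  expect_equal(v[1, 3], -1, tolerance = 1e-12)
  expect_equal(matrixKind(scn), "scn")
  arrBad <- arr
  arrBad[, 4, 1] <- 7
  expect_error(singleFeatureSCN(makeTable(arrBad), "F1"), "parcel 4")
  # independence: unrelated parcels have small |r| on average
  set.seed(5)
  rs <- replicate(100, {
    a2 <- array(rnorm(20 * 3 * 3), dim = c(20, 3, 3))
    simValues(singleFeatureSCN(makeTable(a2), "F1"))[1, 2]
  })
  expect_lte(mean(abs(rs)), 0.3)
})

test_that("MSN pipeline is equivariant and scale invariant", {
  set.seed(6)
  arr <- array(rnorm(5 * 8 * 4), dim = c(5, 8, 4))
  tab <- makeTable(arr)
  gm <- buildGroupMSN(tab)
  # permuting parcels permutes rows/columns identically
  perm <- sample(8)
  gmP <- buildGroupMSN(makeTable(arr[, perm, , drop = FALSE]))
  expect_equal(gmP@values, gm@values[perm, perm], tolerance = 1e-12)
  # permuting features leaves the MSN unchanged
  fperm <- sample(4)
  gmF <- buildGroupMSN(makeTable(arr[, , fperm, drop = FALSE]))
  expect_equal(gmF@values, gm@values, tolerance = 1e-12)
  # positive rescaling of a raw feature is absorbed by the z-score
  arrS <- arr
  arrS[, , 2] <- 100 * arr[, , 2]
  expect_equal(buildGroupMSN(makeTable(arrS))@values, gm@values,
               tolerance = 1e-12)
  scn <- singleFeatureSCN(tab, "F2")
  scnS <- singleFeatureSCN(makeTable(arrS), "F2")
  expect_equal(scnS@values, scn@values, tolerance = 1e-12)
})

test_that("orthogonal module profiles yield block-dominant group MSNs", {
  sc <- cachedScheme(40, seed = 5)
  part <- plantModules(sc, 4, seed = 6)
  cc <- defaultCohortConfig(nSubjects = 8, nParcels = 40, nModules = 4,
                            noiseSd = 1e-6, seed = 7,
                            ageSlopes = rep(0, 8), sexEffects = rep(0, 8))
  coh <- simulateCohort(cc, sc, part)
  gm <- buildGroupMSN(coh$features)
  lab <- membership(part)
  v <- gm@values
  for (a in 1:4) for (b in 1:4) {
    ia <- which(lab == a); ib <- which(lab == b)
    if (a == b) next
    within <- mean(v[ia, ia][upper.tri(v[ia, ia])])
    between <- mean(v[ia, ib])
    expect_gt(within, between)
  }
})
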
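test_that("edge-age analysis finds a planted monotone edge", {
  set.seed(20)
  nS <- 30
  ages <- seq(38, 44, length.out = nS)
  mats <- lapply(seq_len(nS), function(s) {
    v <- matrix(0, 4, 4)
    v[upper.tri(v)] <- c(0.1 + 0.05 * (ages[s] - mean(ages)),  # edge (1,2)
                         runif(5, -0.2, 0.2))
    v <- v + t(v); diag(v) <- 1
    new("SimilarityMatrix", parcels = 1:4, values = v,
        kind = "subject_msn")
  })
  out <- edgeAgeAnalysis(mats, ages)
  e12 <- out$edges[out$edges$i == 1 & out$edges$j == 2, ]
  expect_equal(e12$rho, 1)
  expect_true(e12$significant)
  expect_gte(out$nodeCounts$positive[1], 1)
  expect_gte(out$nodeCounts$positive[2], 1)
  expect_equal(matrixKind(out$edgeAgeMatrix), "edge_age")
  expect_equal(simValues(out$edgeAgeMatrix)[1, 2], 1)
  expect_error(edgeAgeAnalysis(mats, ages[-1]), "align")
})

test_that("node strength equals the off-diagonal row mean oracle", {
  set.seed(21)
  mats <- replicate(5, blockMatrix(c(3, 4), noise = 0.2), simplify = FALSE)
  ns <- nodeStrengths(mats)
  for (s in 1:5) {
    v <- mats[[s]]@values
    for (i in 1:7)
      expect_equal(ns[s, i], mean(v[i, -i]), tolerance = 1e-14)
  }
  # all edges at a node increasing with age: rho = 1 for that node
  ages <- seq(38, 44, length.out = 20)
  mats2 <- lapply(seq_along(ages), function(s) {
    v <- matrix(0.2, 5, 5)
    v[1, -1] <- v[-1, 1] <- 0.2 + 0.05 * (ages[s] - 41)
    v[2, 3] <- v[3, 2] <- 0.2 + 0.01 * rnorm(1)
    diag(v) <- 1
    new("SimilarityMatrix", parcels = 1:5, values = v, kind = "subject_msn")
  })
  outN <- nodeStrengthAgeAnalysis(mats2, ages)
  expect_equal(outN$nodes$rho[1], 1)
  # constant matrices: every statistic missing, empty family
  cst <- replicate(5, blockMatrix(c(2, 3)), simplify = FALSE)
  outC <- nodeStrengthAgeAnalysis(cst, ages[1:5])
  expect_true(all(is.na(outC$nodes$rho)))
  expect_equal(outC$family$size, 0)
})

test_that("sex analysis flags planted male-shifted module edges", {
  set.seed(22)
  nS <- 60
  sexes <- rep(c("M", "F"), nS / 2)
  sizes <- c(5, 5, 5)
  mask <- moduleEdgeMask(sizes, 1)
  mats <- simSubjectMatrices(nS, sizes, sexes = sexes, sexEdges = mask,
                             sexShift = 0.25, noise = 0.05)
  out <- sexAnalysis(mats, sexes)
  inA <- out$edges$i <= 5 & out$edges$j <= 5
  expect_true(all(out$edges$significant[inA]))
  expect_true(all(out$edges$direction[inA] > 0))  # male-higher
  expect_lt(mean(out$edges$significant[!inA]), 0.1)
  expect_true(all(out$nodeCounts$maleHigher[1:5] >= 4))
  expect_error(sexAnalysis(mats, rep("M", nS)), "both sexes")
  # identical matrices for everyone: nothing can be significant
  same <- replicate(8, blockMatrix(c(3, 3)), simplify = FALSE)
  outS <- sexAnalysis(same, rep(c("M", "F"), 4))
  expect_equal(sum(outS$edges$significant, na.rm = TRUE), 0)
  expect_equal(outS$family$edge$size, 0)  # constant series excluded
})

test_that("module strength matches brute-force pair enumeration", {
  # constant matrix: every within/between value equals the constant
  cst <- blockMatrix(c(3, 3), within = 0.3, between = 0.3)
  p <- newPartition(blockLabels(c(3, 3)))
  msC <- moduleStrength(cst, p)
  expect_equal(unname(msC$within), c(0.3, 0.3))
  expect_equal(msC$between["1", "2"], 0.3, ignore_attr = TRUE)
  # 2-block structure
  bl <- blockMatrix(c(4, 3), within = 0.8, between = 0.2)
  msB <- moduleStrength(bl, newPartition(blockLabels(c(4, 3))))
  expect_equal(unname(msB$within), c(0.8, 0.8))
  expect_equal(unname(msB$between["1", "2"]), 0.2)
  # random matrix vs explicit pair loops
  set.seed(23)
  rnd <- blockMatrix(c(3, 4, 2), noise = 0.3)
  lab <- sample(1:3, 9, replace = TRUE)
  lab[1:3] <- 1:3                      # keep all modules non-empty
  ms <- moduleStrength(rnd, newPartition(lab))
  v <- rnd@values
  for (a in 1:3) {
    ia <- which(lab == a)
    if (length(ia) > 1) {
      acc <- c()
      for (x in ia) for (y in ia) if (x < y) acc <- c(acc, v[x, y])
      expect_equal(unname(ms$within[as.character(a)]), mean(acc),
                   tolerance = 1e-14)
    } else {
      expect_true(is.na(ms$within[as.character(a)]))
    }
    for (b in 1:3) {
      if (b <= a) next
      ib <- which(lab == b)
      acc <- c()
      for (x in ia) for (y in ib) acc <- c(acc, v[x, y])
      expect_equal(unname(ms$between[as.character(a), as.character(b)]),
                   mean(acc), tolerance = 1e-14)
    }
  }
})

test_that("module-age analysis flags a planted within-module slope", {
  set.seed(24)
  nS <- 60
  ages <- runif(nS, 37.4, 44.7)
  sizes <- c(6, 6, 6)
  mask <- moduleEdgeMask(sizes, 1)
  mats <- simSubjectMatrices(nS, sizes, ages = ages, slopeEdges = mask,
                             slope = 0.04, noise = 0.05)
  part <- newPartition(blockLabels(sizes))
  out <- moduleAgeAnalysis(mats, part, ages)
  w1 <- out[out$type == "within" & out$moduleA == "1", ]
  expect_true(w1$significant)
  expect_gt(w1$rho, 0)
  # constant matrices: all statistics missing
  cstm <- replicate(6, blockMatrix(c(3, 3)), simplify = FALSE)
  outC <- moduleAgeAnalysis(cstm, newPartition(blockLabels(c(3, 3))),
                            seq(38, 43, length.out = 6))
  expect_true(all(is.na(outC$rho)))
})

test_that("feature-age analysis drops constant series from the family", {
  set.seed(25)
  nS <- 40
  ages <- runif(nS, 37.4, 44.7)
  arr <- array(rnorm(nS * 5 * 3, sd = 0.3), dim = c(nS, 5, 3))
  arr[, , 1] <- arr[, , 1] + outer(ages - mean(ages), rep(0.5, 5))
  arr[, 3, 2] <- 1.5                   # one constant parcel series
  out <- featureAgeAnalysis(makeTable(arr), ages)
  f1 <- out[out$feature == "F1", ]
  expect_true(all(f1$rho > 0))
  expect_gte(mean(f1$significant), 0.8)
  f2c <- out[out$feature == "F2" & out$parcel == 3, ]
  expect_true(is.na(f2c$rho) && is.na(f2c$q))
  expect_false(isTRUE(f2c$significant))
})
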
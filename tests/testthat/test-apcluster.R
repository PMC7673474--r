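test_that("median preference is the off-diagonal median", {
  v <- diag(3)
  v[upper.tri(v)] <- c(0.1, 0.2, 0.3)
  v <- v + t(v); diag(v) <- 1
  expect_equal(medianPreference(v), 0.2)
  u <- matrix(0.37, 4, 4); diag(u) <- 1
  expect_equal(medianPreference(u), 0.37)
  set.seed(1)
  w <- matrix(0, 4, 4)
  w[upper.tri(w)] <- runif(6)
  w <- w + t(w); diag(w) <- 1
  expect_equal(medianPreference(w), mean(sort(w[upper.tri(w)])[3:4]))
})

test_that("affinity propagation solves separable instances optimally", {
  # single point: trivially its own exemplar
  r1 <- affinityPropagation(matrix(0.5, 1, 1))
  expect_equal(r1@k, 1)
  expect_equal(exemplars(r1), 1L)

  # two groups of 4: k = 2, labels match, objective equals the brute-force
  # optimum over all exemplar subsets
  m <- blockMatrix(c(4, 4), within = 0.9, between = 0.1)
  res <- affinityPropagation(m)
  expect_true(res@converged)
  expect_equal(res@k, 2)
  expect_equal(normalizedVI(res@partition, newPartition(blockLabels(c(4, 4)))),
               0)
  bf <- bruteForceNet(m@values, medianPreference(m))
  expect_equal(res@netSimilarity, bf$net, tolerance = 1e-8)

  # uniform similarities with a deeply negative preference: one cluster
  u <- matrix(0.5, 6, 6); diag(u) <- 1
  cfg <- apConfig(preference = -10)
  resU <- suppressWarnings(affinityPropagation(u, cfg))
  expect_equal(resU@k, 1)
  bfU <- bruteForceNet(u, -10)
  expect_equal(length(bfU$exemplars), 1)
  expect_equal(resU@netSimilarity, bfU$net, tolerance = 1e-8)

  expect_error(affinityPropagation(matrix(0, 2, 3)), "square")
})

test_that("fixed-k search hits the requested cluster count", {
  m <- blockMatrix(c(5, 5, 5), within = 0.8, between = 0.1)
  res <- clusterFixedK(m, 3)
  expect_equal(res@k, 3)
  expect_equal(normalizedVI(res@partition,
                            newPartition(blockLabels(c(5, 5, 5)))), 0)
  bf <- bruteForceNet(m@values, res@preference)
  expect_equal(res@netSimilarity, bf$net, tolerance = 1e-8)

  expect_equal(clusterFixedK(m, 1)@k, 1)       # low-preference limit
  expect_equal(clusterFixedK(m, 15)@k, 15)     # high-preference limit
  expect_error(clusterFixedK(m, 0), "kTarget")
})

test_that("achieved k is non-decreasing in the preference", {
  set.seed(2)
  m <- blockMatrix(c(4, 4, 4), within = 0.7, between = 0.2, noise = 0.05)
  off <- m@values[upper.tri(m@values)]
  grid <- seq(min(off) - diff(range(off)), max(off), length.out = 9)
  ks <- vapply(grid, function(p)
    suppressWarnings(affinityPropagation(m, apConfig(preference = p)))@k,
    integer(1))
  expect_true(all(diff(ks) >= 0))
})

test_that("well-separated solutions do not depend on damping", {
  m <- blockMatrix(c(5, 5), within = 0.85, between = 0.1)
  r1 <- affinityPropagation(m, apConfig(damping = 0.5))
  r2 <- affinityPropagation(m, apConfig(damping = 0.9))
  expect_equal(normalizedVI(r1@partition, r2@partition), 0)
  expect_equal(r1@k, r2@k)
})

test_that("bootstrap coincidence reflects the block structure", {
  mats <- replicate(10, blockMatrix(c(3, 3), within = 0.9, between = 0.1),
                    simplify = FALSE)
  cm <- bootstrapStability(mats, drawSize = 4, iterations = 20, seed = 3)
  v <- simValues(cm)
  lab <- blockLabels(c(3, 3))
  same <- outer(lab, lab, "==")
  expect_true(all(v[same] == 1))
  expect_true(all(v[!same] == 0))
  one <- bootstrapStability(mats, drawSize = 4, iterations = 1, seed = 4)
  expect_true(all(simValues(one) %in% c(0, 1)))
  expect_error(bootstrapStability(list(), 2, 2), "empty")
  expect_error(bootstrapStability(mats, drawSize = 99), "drawSize")
})

test_that("planted cohorts give high within-module bootstrap coincidence", {
  wb <- sapply(1:3, function(s) {
    sc <- cachedScheme(42, seed = s)
    cc <- defaultCohortConfig(nSubjects = 60, nParcels = 42, nModules = 7,
                              noiseSd = 0.5, seed = s)
    coh <- simulateCohort(cc, sc)
    sm <- subjectMSNs(zscoreFeatures(coh$features))
    cm <- bootstrapStability(sm, drawSize = 20, iterations = 50,
                             kTarget = 7, seed = s)
    v <- simValues(cm)
    lab <- membership(coh$truth@modulePartition)
    same <- outer(lab, lab, "==")
    diag(same) <- NA
    c(within = mean(v[which(same)]), between = mean(v[which(!same)]))
  })
  expect_true(all(wb["within", ] >= 0.9))
  expect_true(all(wb["within", ] >= 2 * wb["between", ]))
})

test_that("individual subjects reproduce the group partition closely", {
  meds <- sapply(1:3, function(s) {
    sc <- cachedScheme(60, seed = 10 + s)
    cc <- defaultCohortConfig(nSubjects = 6, nParcels = 60, nModules = 7,
                              noiseSd = 0.5, seed = 10 + s)
    coh <- simulateCohort(cc, sc)
    sm <- subjectMSNs(zscoreFeatures(coh$features))
    gp <- clusterFixedK(groupMSN(sm), 7)@partition
    median(clusterSubjects(sm, gp, kTarget = 7)$nvi, na.rm = TRUE)
  })
  expect_true(all(meds <= 0.2))
})

test_that("per-subject clustering consistency is NVI against the group", {
  m <- blockMatrix(c(4, 4), within = 0.9, between = 0.1)
  group <- newPartition(blockLabels(c(4, 4)))
  out <- clusterSubjects(list(a = m, b = m), group, kTarget = 2)
  expect_equal(out$nvi, c(0, 0))
  # relabel invariance
  flipped <- newPartition(3 - blockLabels(c(4, 4)))
  expect_equal(normalizedVI(group, flipped), 0)
})

test_that("edge-age matrix clustering recovers maturation blocks", {
  # regions whose edges mature alike are mutually rho-similar: planted
  # 2-block pattern, within-block rho 0.8, cross 0
  lab <- blockLabels(c(6, 6))
  rhoM <- ifelse(outer(lab, lab, "=="), 0.8, 0.0)
  diag(rhoM) <- 0
  em <- new("SimilarityMatrix", parcels = seq_along(lab),
            values = rhoM, kind = "edge_age")
  res <- clusterEdgeAgeMatrix(em, kTarget = 2)
  expect_equal(res@k, 2)
  expect_equal(normalizedVI(res@partition, newPartition(lab)), 0)

  cst <- new("SimilarityMatrix", parcels = 1:5,
             values = matrix(0.3, 5, 5) - 0.3 * diag(5) + 0.3 * diag(5),
             kind = "edge_age")
  # constant off-diagonal: the objective is flat in k (any single
  # exemplar attains the optimum), so check the objective, not k
  cstRes <- clusterEdgeAgeMatrix(cst)
  bf <- bruteForceNet(cst@values, medianPreference(cst))
  expect_equal(length(bf$exemplars), 1)
  expect_equal(cstRes@netSimilarity, bf$net, tolerance = 1e-8)

  # permutation equivariance
  perm <- c(3, 1, 2, 5, 4, 6, 9, 7, 8, 12, 10, 11)
  emP <- new("SimilarityMatrix", parcels = seq_along(lab),
             values = rhoM[perm, perm], kind = "edge_age")
  resP <- clusterEdgeAgeMatrix(emP, kTarget = 2)
  expect_equal(normalizedVI(resP@partition,
                            newPartition(lab[perm])), 0)
  expect_error(clusterEdgeAgeMatrix(blockMatrix(c(3, 3))), "edge_age")
})
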
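# Shared fixtures and independent oracles. Schemes are cached per session
# because Lloyd relaxation is the slowest fixture to build.

.schemeCache <- new.env(parent = emptyenv())

cachedScheme <- function(n, seed = 1, nMonteCarlo = 2e4) {
  key <- sprintf("s%d_%d_%g", n, seed, nMonteCarlo)
  if (is.null(.schemeCache[[key]]))
    .schemeCache[[key]] <- makeParcellation(n, seed = seed,
                                            nMonteCarlo = nMonteCarlo)
  .schemeCache[[key]]
}

# Block similarity matrix: sizes per block, within/between values, unit
# diagonal; optional symmetric noise.
blockMatrix <- function(sizes, within = 0.8, between = 0.1, noise = 0,
                        kind = "group_msn") {
  n <- sum(sizes)
  lab <- rep(seq_along(sizes), sizes)
  v <- ifelse(outer(lab, lab, "=="), within, between)
  if (noise > 0) {
    e <- matrix(stats::rnorm(n * n, sd = noise), n, n)
    v <- v + (e + t(e)) / 2
    v <- pmax(pmin(v, 1), -1)
  }
  diag(v) <- 1
  new("SimilarityMatrix", parcels = seq_len(n), values = v, kind = kind)
}

blockLabels <- function(sizes) rep(seq_along(sizes), sizes)

# FeatureTable from a subjects x parcels x features array.
makeTable <- function(arr, zscored = FALSE) {
  d <- dim(arr)
  if (is.null(dimnames(arr)))
    dimnames(arr) <- list(sprintf("s%02d", seq_len(d[1])), seq_len(d[2]),
                          sprintf("F%d", seq_len(d[3])))
  new("FeatureTable", values = arr, zscored = zscored)
}

# Independent VI oracle: explicit double loop over label pairs, no shared
# code with the implementation.
viOracle <- function(p, q) {
  n <- length(p)
  H <- function(sizes) {
    pr <- sizes / n
    -sum(ifelse(pr > 0, pr * log2(pr), 0))
  }
  pl <- unique(p); ql <- unique(q)
  joint <- c()
  for (a in pl) for (b in ql) joint <- c(joint, sum(p == a & q == b))
  hP <- H(vapply(pl, function(a) sum(p == a), numeric(1)))
  hQ <- H(vapply(ql, function(b) sum(q == b), numeric(1)))
  hJ <- H(joint[joint > 0])
  mi <- hP + hQ - hJ
  list(vi = hP + hQ - 2 * mi, nvi = if (hJ == 0) 0 else (hP + hQ - 2 * mi) / hJ)
}

# Exhaustive exemplar-set maximisation of the affinity-propagation
# objective (feasible for n <= ~15).
bruteForceNet <- function(v, preference) {
  n <- nrow(v)
  best <- -Inf
  bestSet <- NULL
  for (mask in 1:(2^n - 1)) {
    ex <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    net <- netSimilarityOf(v, ex, preference)
    if (net > best) { best <- net; bestSet <- ex }
  }
  list(net = best, exemplars = bestSet)
}

# Random partition of n items into at most k non-trivially-sized groups.
randomPartition <- function(n, k) {
  newPartition(sample.int(k, n, replace = TRUE))
}

# Direct-construction subject matrices: base block structure plus optional
# per-edge age slope or sex shift, plus symmetric noise.
simSubjectMatrices <- function(nSubjects, sizes, ages = NULL, sexes = NULL,
                               slopeEdges = NULL, slope = 0,
                               sexEdges = NULL, sexShift = 0,
                               within = 0.6, between = 0.1, noise = 0.05) {
  n <- sum(sizes)
  lab <- blockLabels(sizes)
  base <- ifelse(outer(lab, lab, "=="), within, between)
  lapply(seq_len(nSubjects), function(s) {
    v <- base
    if (!is.null(slopeEdges) && !is.null(ages))
      v[slopeEdges] <- v[slopeEdges] + slope * (ages[s] - mean(ages))
    if (!is.null(sexEdges) && !is.null(sexes) && sexes[s] == "M")
      v[sexEdges] <- v[sexEdges] + sexShift
    e <- matrix(stats::rnorm(n * n, sd = noise), n, n)
    v <- v + (e + t(e)) / 2
    v <- pmax(pmin(v, 1), -1)
    v <- (v + t(v)) / 2
    diag(v) <- 1
    new("SimilarityMatrix", parcels = seq_len(n), values = v,
        kind = "subject_msn")
  })
}

# Logical matrix selecting within-module edges (both endpoints in module m).
moduleEdgeMask <- function(sizes, m) {
  lab <- blockLabels(sizes)
  sel <- outer(lab == m, lab == m, "&")
  diag(sel) <- FALSE
  sel
}
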
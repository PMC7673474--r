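#' @include AllClasses.R stats.R
NULL

# Stack the upper triangles of per-subject matrices into a subjects x
# edges matrix; returns the pair index alongside.
.edgeMatrix <- function(subjectMatrices) {
  p0 <- parcelIds(subjectMatrices[[1]])
  n <- length(p0)
  pairs <- upperPairs(n)
  E <- vapply(subjectMatrices, function(m) {
    if (!identical(parcelIds(m), p0)) stop("mismatched parcel orderings")
    m@values[upper.tri(m@values)]
  }, numeric(nrow(pairs)))
  list(edges = t(E), pairs = pairs, parcels = p0, n = n)
}

#' Edgewise age association analysis
#'
#' Spearman correlation between every MSN edge (across subjects) and age,
#' corrected over the family of upper-triangle edges. Also tallies, per
#' node, the number of significant positive and negative edges, and emits
#' the full rho matrix (kind \code{edge_age}) for downstream clustering of
#' maturational similarity.
#'
#' @param subjectMatrices list of per-subject
#'   \linkS4class{SimilarityMatrix} (>= 3 subjects).
#' @param ages numeric vector aligned with the subject list.
#' @param correction \code{"pfdr"} (Storey q-values, the default for edge
#'   and node families) or \code{"bh"}.
#' @param q significance level on q-values.
#' @return list: \code{edges} (data.frame i, j, rho, p, q, significant,
#'   direction), \code{nodeCounts} (data.frame node, positive, negative),
#'   \code{edgeAgeMatrix} (\linkS4class{SimilarityMatrix}), and
#'   \code{family} metadata.
#' @export
edgeAgeAnalysis <- function(subjectMatrices, ages, correction = "pfdr",
                            q = 0.05) {
  if (length(subjectMatrices) < 3) stop("need at least 3 subjects")
  if (length(ages) != length(subjectMatrices))
    stop("ages must align with subject matrices")
  em <- .edgeMatrix(subjectMatrices)
  sp <- .spearmanCols(em$edges, ages)
  corr <- .correctFamily(sp$p, method = correction, q = q)
  edges <- data.frame(
    i = em$parcels[em$pairs[, 1]], j = em$parcels[em$pairs[, 2]],
    rho = sp$rho, p = sp$p, q = corr$q, significant = corr$significant,
    direction = sign(sp$rho))
  rhoM <- matrix(0, em$n, em$n)
  rhoM[upper.tri(rhoM)] <- ifelse(is.na(sp$rho), 0, sp$rho)
  rhoM <- rhoM + t(rhoM)
  nodeCounts <- data.frame(
    node = em$parcels,
    positive = vapply(seq_len(em$n), function(v) {
      sum(edges$significant & edges$direction > 0 &
            (em$pairs[, 1] == v | em$pairs[, 2] == v))
    }, integer(1)),
    negative = vapply(seq_len(em$n), function(v) {
      sum(edges$significant & edges$direction < 0 &
            (em$pairs[, 1] == v | em$pairs[, 2] == v))
    }, integer(1)))
  list(edges = edges, nodeCounts = nodeCounts,
       edgeAgeMatrix = newSimilarityMatrix(rhoM, kind = "edge_age",
                                           parcels = em$parcels),
       family = list(unit = "edge", method = correction, q = q,
                     size = corr$familySize))
}

#' Node-strength age association analysis
#'
#' Node strength is the mean of a node's edges (off-diagonal row mean) in
#' each subject's matrix; each node's strength series is correlated with
#' age (Spearman) and corrected over the node family.
#'
#' @inheritParams edgeAgeAnalysis
#' @return list: \code{nodes} (data.frame node, rho, p, q, significant,
#'   direction) and \code{family} metadata.
#' @export
nodeStrengthAgeAnalysis <- function(subjectMatrices, ages,
                                    correction = "pfdr", q = 0.05) {
  if (length(subjectMatrices) < 3) stop("need at least 3 subjects")
  if (length(ages) != length(subjectMatrices))
    stop("ages must align with subject matrices")
  p0 <- parcelIds(subjectMatrices[[1]])
  ns <- nodeStrengths(subjectMatrices)
  sp <- .spearmanCols(ns, ages)
  corr <- .correctFamily(sp$p, method = correction, q = q)
  list(nodes = data.frame(node = p0, rho = sp$rho, p = sp$p, q = corr$q,
                          significant = corr$significant,
                          direction = sign(sp$rho)),
       family = list(unit = "node", method = correction, q = q,
                     size = corr$familySize))
}

#' Per-subject node strengths
#'
#' @param subjectMatrices list of \linkS4class{SimilarityMatrix}.
#' @return subjects x nodes numeric matrix of off-diagonal row means.
#' @export
nodeStrengths <- function(subjectMatrices) {
  p0 <- parcelIds(subjectMatrices[[1]])
  n <- length(p0)
  t(vapply(subjectMatrices, function(m) {
    v <- m@values
    (rowSums(v) - diag(v)) / (n - 1)
  }, numeric(n)))
}

#' Sex difference analysis for edges and node strengths
#'
#' Mann-Whitney tests of male vs female subjects for every edge and every
#' node strength, each family corrected separately. Direction is the sign
#' of the male-vs-female rank shift (U relative to its null mean), so
#' positive means male-higher.
#'
#' @param subjectMatrices list of per-subject
#'   \linkS4class{SimilarityMatrix}.
#' @param sexes character vector of \code{"M"}/\code{"F"} aligned with the
#'   subjects.
#' @param correction,q as in \code{\link{edgeAgeAnalysis}}.
#' @return list: \code{edges}, \code{nodes} (data.frames with U, p, q,
#'   significant, direction), \code{nodeCounts} of significant edges by
#'   direction, and \code{family} metadata per family.
#' @export
sexAnalysis <- function(subjectMatrices, sexes, correction = "pfdr",
                        q = 0.05) {
  if (length(sexes) != length(subjectMatrices))
    stop("sexes must align with subject matrices")
  male <- sexes == "M"
  if (!any(male) || all(male)) stop("both sexes must be present")
  em <- .edgeMatrix(subjectMatrices)
  mw <- function(col) {
    res <- mannWhitney(col[male], col[!male])
    c(res$U, res$p, sign(res$U - sum(male) * sum(!male) / 2))
  }
  edgeStats <- apply(em$edges, 2, mw)
  corrE <- .correctFamily(.naConst(em$edges, edgeStats[2, ]),
                          method = correction, q = q)
  edges <- data.frame(
    i = em$parcels[em$pairs[, 1]], j = em$parcels[em$pairs[, 2]],
    U = edgeStats[1, ], p = edgeStats[2, ], q = corrE$q,
    significant = corrE$significant, direction = edgeStats[3, ])
  ns <- nodeStrengths(subjectMatrices)
  nodeStats <- apply(ns, 2, mw)
  corrN <- .correctFamily(.naConst(ns, nodeStats[2, ]),
                          method = correction, q = q)
  nodes <- data.frame(node = em$parcels, U = nodeStats[1, ],
                      p = nodeStats[2, ], q = corrN$q,
                      significant = corrN$significant,
                      direction = nodeStats[3, ])
  nodeCounts <- data.frame(
    node = em$parcels,
    maleHigher = vapply(seq_len(em$n), function(v) {
      sum(edges$significant & edges$direction > 0 &
            (em$pairs[, 1] == v | em$pairs[, 2] == v))
    }, integer(1)),
    femaleHigher = vapply(seq_len(em$n), function(v) {
      sum(edges$significant & edges$direction < 0 &
            (em$pairs[, 1] == v | em$pairs[, 2] == v))
    }, integer(1)))
  list(edges = edges, nodes = nodes, nodeCounts = nodeCounts,
       family = list(edge = list(unit = "edge", method = correction, q = q,
                                 size = corrE$familySize),
                     node = list(unit = "node", method = correction, q = q,
                                 size = corrN$familySize)))
}

# Mark p as missing for constant series (Mann-Whitney on a constant column
# is uninformative; exclude it from the family like the Spearman path).
.naConst <- function(X, p) {
  constant <- apply(X, 2, function(col) all(col == col[1]))
  p[constant] <- NA_real_
  p
}

#' Within- and between-module mean edge strength
#'
#' For one similarity matrix and a module partition: within(c) is the mean
#' over unordered parcel pairs inside module c (missing for singleton
#' modules), between(c, d) the mean over pairs crossing modules c and d.
#' The diagonal never contributes.
#'
#' @param matrix a \linkS4class{SimilarityMatrix}.
#' @param partition a \linkS4class{Partition} over the same parcels.
#' @return list with named numeric \code{within} (per module) and
#'   \code{between} (matrix indexed by module pairs).
#' @export
moduleStrength <- function(matrix, partition) {
  if (!identical(parcelIds(matrix), partition@parcels))
    stop("matrix and partition are defined over different parcels")
  v <- matrix@values
  lab <- partition@labels
  mods <- sort(unique(lab))
  K <- length(mods)
  within <- stats::setNames(rep(NA_real_, K), mods)
  between <- base::matrix(NA_real_, K, K, dimnames = list(mods, mods))
  for (a in seq_len(K)) {
    ia <- which(lab == mods[a])
    if (length(ia) > 1) {
      sub <- v[ia, ia]
      within[a] <- mean(sub[upper.tri(sub)])
    }
    for (b in seq_len(K)) {
      if (b <= a) next
      ib <- which(lab == mods[b])
      between[a, b] <- between[b, a] <- mean(v[ia, ib])
    }
  }
  list(within = within, between = between)
}

#' Module-level age association analysis
#'
#' Per subject, within- and between-module mean edge strengths (module
#' integration/segregation measures); each series is correlated with age
#' (Spearman) and the combined within + between family is BH-FDR
#' corrected.
#'
#' @param subjectMatrices list of per-subject
#'   \linkS4class{SimilarityMatrix}.
#' @param partition module \linkS4class{Partition}.
#' @param ages numeric vector aligned with subjects.
#' @param q FDR level.
#' @return data.frame with columns type ("within"/"between"), moduleA,
#'   moduleB (NA for within), rho, p, q, significant, direction.
#' @export
moduleAgeAnalysis <- function(subjectMatrices, partition, ages, q = 0.05) {
  if (length(subjectMatrices) < 3) stop("need at least 3 subjects")
  if (length(ages) != length(subjectMatrices))
    stop("ages must align with subject matrices")
  per <- lapply(subjectMatrices, moduleStrength, partition = partition)
  mods <- names(per[[1]]$within)
  K <- length(mods)
  rows <- list()
  for (a in seq_len(K)) {
    series <- vapply(per, function(x) x$within[a], numeric(1))
    rows[[length(rows) + 1]] <- list(type = "within", moduleA = mods[a],
                                     moduleB = NA_character_,
                                     series = series)
  }
  for (a in seq_len(K)) for (b in seq_len(K)) {
    if (b <= a) next
    series <- vapply(per, function(x) x$between[a, b], numeric(1))
    rows[[length(rows) + 1]] <- list(type = "between", moduleA = mods[a],
                                     moduleB = mods[b], series = series)
  }
  stat <- lapply(rows, function(r) {
    if (anyNA(r$series) || stats::sd(r$series) == 0)
      return(list(rho = NA_real_, p = NA_real_))
    spearmanRho(r$series, ages)
  })
  p <- vapply(stat, `[[`, numeric(1), "p")
  corr <- .correctFamily(p, method = "bh", q = q)
  data.frame(
    type = vapply(rows, `[[`, character(1), "type"),
    moduleA = vapply(rows, `[[`, character(1), "moduleA"),
    moduleB = vapply(rows, `[[`, character(1), "moduleB"),
    rho = vapply(stat, `[[`, numeric(1), "rho"),
    p = p, q = corr$q, significant = corr$significant,
    direction = sign(vapply(stat, `[[`, numeric(1), "rho")),
    stringsAsFactors = FALSE)
}

#' Single-feature regional age association analysis
#'
#' Spearman correlation of each (parcel, feature) raw series against age,
#' BH-FDR corrected within each feature's family of parcels.
#'
#' @param rawTable raw \linkS4class{FeatureTable}.
#' @param ages numeric vector aligned with subjects.
#' @param q FDR level.
#' @return data.frame with columns feature, parcel, rho, p, q,
#'   significant, direction.
#' @export
featureAgeAnalysis <- function(rawTable, ages, q = 0.05) {
  v <- featureValues(rawTable)
  if (dim(v)[1] != length(ages))
    stop("ages must align with subjects")
  feats <- featureNames(rawTable)
  parcels <- parcelIds(rawTable)
  out <- lapply(feats, function(f) {
    X <- v[, , f]
    sp <- .spearmanCols(X, ages)
    corr <- .correctFamily(sp$p, method = "bh", q = q)
    data.frame(feature = f, parcel = parcels, rho = sp$rho, p = sp$p,
               q = corr$q, significant = corr$significant,
               direction = sign(sp$rho), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
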
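#' @include AllClasses.R
NULL

.checkAligned <- function(P, Q) {
  if (!identical(P@parcels, Q@parcels))
    stop("partitions are defined over different parcel sets")
}

.contingency <- function(P, Q) {
  table(factor(P@labels), factor(Q@labels))
}

#' Variation of information between two partitions
#'
#' The information-theoretic partition distance
#' \eqn{VI = H(P) + H(Q) - 2 I(P, Q)} computed from the label contingency
#' table, in bits. A true metric on the space of partitions: zero iff the
#' partitions coincide up to relabelling.
#'
#' @param P,Q \linkS4class{Partition}s over the same parcels.
#' @return non-negative numeric scalar (bits).
#' @export
variationOfInformation <- function(P, Q) {
  .checkAligned(P, Q)
  tab <- .contingency(P, Q)
  hP <- entropyBits(rowSums(tab))
  hQ <- entropyBits(colSums(tab))
  hJ <- entropyBits(tab)
  mi <- hP + hQ - hJ
  max(0, hP + hQ - 2 * mi)
}

#' Normalized variation of information
#'
#' VI divided by the joint entropy (the entropy of the cell-wise
#' intersection partition), giving a dissimilarity in [0, 1]: 0 for
#' identical partitions (up to relabelling), 1 for independent ones.
#' Defined as 0 when both partitions are trivial (joint entropy 0).
#'
#' @param P,Q \linkS4class{Partition}s over the same parcels.
#' @return numeric in [0, 1]; lower means more similar.
#' @export
normalizedVI <- function(P, Q) {
  .checkAligned(P, Q)
  tab <- .contingency(P, Q)
  hJ <- entropyBits(tab)
  if (hJ == 0) return(0)
  vi <- variationOfInformation(P, Q)
  min(1, max(0, vi / hJ))
}

#' Dice overlap table between two labellings
#'
#' Entry (k, c) is \eqn{2 |P_k \cap Q_c| / (|P_k| + |Q_c|)}: the spatial
#' overlap of cluster k with reference class c.
#'
#' @param P,Q \linkS4class{Partition}s over the same parcels.
#' @return K x C numeric matrix, rows/cols named by the sorted labels of
#'   P and Q.
#' @export
diceOverlap <- function(P, Q) {
  .checkAligned(P, Q)
  kl <- sort(unique(P@labels))
  cl <- sort(unique(Q@labels))
  tab <- as.matrix(table(factor(P@labels, levels = kl),
                         factor(Q@labels, levels = cl)))
  sizesP <- rowSums(tab)
  sizesQ <- colSums(tab)
  d <- 2 * tab / outer(sizesP, sizesQ, "+")
  dimnames(d) <- list(kl, cl)
  d
}

#' Spherical spin-permutation test for partition correspondence
#'
#' Tests whether two parcel labellings agree more than expected for maps
#' with the same spatial structure placed at random relative orientation.
#' Each permutation applies a uniformly random rotation to the sphere,
#' carries Q's labels through a nearest-centroid (great-circle) mapping
#' (each parcel takes the label of the parcel nearest to its rotated
#' centroid), and records NVI(P, rotated Q). Because smaller NVI means
#' better agreement, the p-value counts nulls at least as small as the
#' observed value, with the add-one convention
#' \eqn{p = (1 + \#\{null \le obs\}) / (1 + n_{perm})}.
#'
#' The nearest-centroid mapping is many-to-one, so rotated label counts
#' deviate slightly from Q's; the per-permutation deviation fraction is
#' reported in the result. Note that maps sharing a genuine spatial
#' alignment beyond chance - e.g. two labellings that are both
#' mirror-symmetric about the same interhemispheric plane - are
#' correctly detected as corresponding, because rotations destroy that
#' shared axis.
#'
#' @param scheme the \linkS4class{ParcelScheme} both labellings live on.
#' @param P,Q \linkS4class{Partition}s aligned with the scheme.
#' @param nPerm number of random rotations.
#' @param seed RNG seed.
#' @return a \linkS4class{SpinTestResult}.
#' @export
spinTest <- function(scheme, P, Q, nPerm = 500L, seed = 1L) {
  .checkAligned(P, Q)
  if (nPerm < 1) stop("nPerm must be >= 1")
  cen <- centroids(scheme)
  if (nParcels(scheme) != length(P@parcels))
    stop("scheme and partitions are not aligned")
  g <- cen %*% t(cen)
  if (any(g[upper.tri(g)] > 1 - 1e-12))
    stop("degenerate scheme: duplicate centroids")
  observed <- normalizedVI(P, Q)
  qlab <- Q@labels
  qLevels <- sort(unique(qlab))
  baseCounts <- tabulate(factor(qlab, levels = qLevels),
                         nbins = length(qLevels))
  nulls <- numeric(nPerm)
  dev <- numeric(nPerm)
  n <- length(qlab)
  withSeed(stageSeed(seed, "spin"), {
    for (b in seq_len(nPerm)) {
      rot <- randomRotation()
      rc <- cen %*% t(rot)
      nearest <- max.col(rc %*% t(cen), ties.method = "first")
      qRot <- qlab[nearest]
      nulls[b] <- normalizedVI(P, newPartition(qRot, P@parcels))
      rotCounts <- tabulate(factor(qRot, levels = qLevels),
                            nbins = length(qLevels))
      dev[b] <- sum(abs(rotCounts - baseCounts)) / (2 * n)
    }
  })
  p <- (1 + sum(nulls <= observed)) / (1 + nPerm)
  new("SpinTestResult", observed = observed, nullStats = nulls,
      pValue = p, nPerm = as.integer(nPerm), seed = as.integer(seed),
      countDeviation = dev)
}
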
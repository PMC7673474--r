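#' @include AllClasses.R
NULL

#' Z-score features across the cortex
#'
#' For every subject and feature, values are standardised across parcels to
#' mean 0 and sample standard deviation 1 (n - 1 denominator). This puts
#' the eight morphometric features on a common scale before regional
#' profiles are correlated.
#'
#' @param table a raw \linkS4class{FeatureTable}.
#' @return a z-scored \linkS4class{FeatureTable}.
#' @export
zscoreFeatures <- function(table) {
  v <- featureValues(table)
  d <- dim(v)
  out <- v
  for (f in seq_len(d[3])) {
    slab <- v[, , f, drop = FALSE]
    dim(slab) <- d[1:2]
    mu <- rowMeans(slab)
    sdv <- apply(slab, 1, stats::sd)
    bad <- which(sdv == 0)
    if (length(bad))
      stop(sprintf(
        "zero variance across parcels for subject '%s', feature '%s'",
        subjectIds(table)[bad[1]], featureNames(table)[f]))
    out[, , f] <- (slab - mu) / sdv
  }
  new("FeatureTable", values = out, zscored = TRUE)
}

#' Per-subject morphometric similarity network
#'
#' Edge (i, j) is the Pearson correlation between the F-dimensional
#' z-scored feature vectors of parcels i and j for one subject. The
#' diagonal is fixed to 1.
#'
#' @param ztable a z-scored \linkS4class{FeatureTable}.
#' @param subject subject id (or index).
#' @return a \linkS4class{SimilarityMatrix} of kind \code{subject_msn}.
#' @export
subjectMSN <- function(ztable, subject) {
  v <- featureValues(ztable)
  if (is.character(subject)) {
    subject <- match(subject, subjectIds(ztable))
    if (is.na(subject)) stop("unknown subject id")
  }
  X <- v[subject, , ]               # parcels x features
  .profileCorrelation(X, parcelIds(ztable), kind = "subject_msn")
}

.profileCorrelation <- function(X, parcels, kind) {
  sdv <- apply(X, 1, stats::sd)
  bad <- which(sdv == 0)
  if (length(bad))
    stop(sprintf("constant feature vector at parcel %d", parcels[bad[1]]))
  r <- stats::cor(t(X))
  diag(r) <- 1
  r[r > 1] <- 1; r[r < -1] <- -1
  newSimilarityMatrix(r, kind = kind, parcels = parcels)
}

#' All per-subject MSNs of a cohort
#'
#' @param ztable a z-scored \linkS4class{FeatureTable}.
#' @return list of \linkS4class{SimilarityMatrix}, one per subject, named
#'   by subject id.
#' @export
subjectMSNs <- function(ztable) {
  ids <- subjectIds(ztable)
  out <- lapply(seq_along(ids), function(s) subjectMSN(ztable, s))
  names(out) <- ids
  out
}

#' Group-average similarity network
#'
#' Element-wise mean of per-subject similarity matrices; the group MSN the
#' clustering operates on.
#'
#' @param matrices non-empty list of \linkS4class{SimilarityMatrix} over a
#'   common parcel ordering.
#' @return a \linkS4class{SimilarityMatrix} of kind \code{group_msn}.
#' @export
groupMSN <- function(matrices) {
  if (!length(matrices)) stop("empty matrix list")
  p0 <- parcelIds(matrices[[1]])
  acc <- matrix(0, length(p0), length(p0))
  for (m in matrices) {
    if (!identical(parcelIds(m), p0))
      stop("matrices have mismatched parcel orderings")
    acc <- acc + m@values
  }
  acc <- acc / length(matrices)
  diag(acc) <- 1
  newSimilarityMatrix(acc, kind = "group_msn", parcels = p0)
}

#' Group MSN from a raw feature table
#'
#' Convenience composition: z-score, per-subject MSNs, group average.
#'
#' @param table a raw \linkS4class{FeatureTable}.
#' @return a \linkS4class{SimilarityMatrix} of kind \code{group_msn}.
#' @export
buildGroupMSN <- function(table) {
  groupMSN(subjectMSNs(zscoreFeatures(table)))
}

#' Leave-one-feature-out group MSN
#'
#' Re-runs the full pipeline (z-score, subject MSNs, group average) on the
#' table with one feature removed; used to rank the contribution of each
#' imaging feature to the clustering solution.
#'
#' @param table raw \linkS4class{FeatureTable} with >= 4 features.
#' @param excludedFeature feature name to drop.
#' @return a \linkS4class{SimilarityMatrix} of kind \code{group_msn}.
#' @export
leaveOneOutGroupMSN <- function(table, excludedFeature) {
  feats <- featureNames(table)
  if (!excludedFeature %in% feats)
    stop(sprintf("unknown feature '%s'", excludedFeature))
  keep <- setdiff(feats, excludedFeature)
  if (length(keep) < 3)
    stop("fewer than 3 features would remain")
  v <- featureValues(table)[, , keep, drop = FALSE]
  buildGroupMSN(new("FeatureTable", values = v, zscored = FALSE))
}

#' Single-feature structural covariance network
#'
#' Classical SCN: edge (i, j) is the Pearson correlation, across subjects,
#' between the raw (un-normalised) values of one feature at parcels i and
#' j. A group-level construct, unlike the per-subject MSN.
#'
#' @param rawTable raw \linkS4class{FeatureTable} with >= 3 subjects.
#' @param feature feature name.
#' @return a \linkS4class{SimilarityMatrix} of kind \code{scn}.
#' @export
singleFeatureSCN <- function(rawTable, feature) {
  feats <- featureNames(rawTable)
  if (!feature %in% feats) stop(sprintf("unknown feature '%s'", feature))
  v <- featureValues(rawTable)
  if (dim(v)[1] < 3) stop("need at least 3 subjects")
  X <- v[, , feature]               # subjects x parcels
  sdv <- apply(X, 2, stats::sd)
  bad <- which(sdv == 0)
  if (length(bad))
    stop(sprintf("zero cross-subject variance at parcel %d",
                 parcelIds(rawTable)[bad[1]]))
  r <- stats::cor(X)
  diag(r) <- 1
  r[r > 1] <- 1; r[r < -1] <- -1
  newSimilarityMatrix(r, kind = "scn", parcels = parcelIds(rawTable))
}
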
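#' @import methods
#' @include AllGenerics.R
NULL

.near <- function(a, b, tol) abs(a - b) <= tol

#' ParcelScheme: a spherical cortical parcellation
#'
#' Holds the geometric substrate for the whole pipeline: parcel centroids on
#' the unit sphere, hemisphere labels (sign of the x-coordinate) and relative
#' Voronoi area weights. Produced by \code{\link{makeParcellation}}.
#'
#' @slot parcelId integer vector, contiguous \code{1..n}.
#' @slot centroids n x 3 numeric matrix of unit-norm centroid coordinates.
#' @slot hemisphere character vector, \code{"L"} (x < 0) or \code{"R"}.
#' @slot areaWeight numeric vector of relative areas, summing to 1.
#'
#' @export
setClass("ParcelScheme",
  representation(
    parcelId = "integer",
    centroids = "matrix",
    hemisphere = "character",
    areaWeight = "numeric"
  )
)

setValidity("ParcelScheme", function(object) {
  n <- length(object@parcelId)
  msg <- character()
  if (!identical(object@parcelId, seq_len(n)))
    msg <- c(msg, "parcel ids must be contiguous 1..n")
  if (!is.numeric(object@centroids) || !identical(dim(object@centroids), c(n, 3L)))
    msg <- c(msg, "centroids must be an n x 3 numeric matrix")
  else {
    nrm <- sqrt(rowSums(object@centroids^2))
    if (any(abs(nrm - 1) > 1e-9))
      msg <- c(msg, "all centroids must have unit norm (tol 1e-9)")
  }
  if (length(object@hemisphere) != n || !all(object@hemisphere %in% c("L", "R")))
    msg <- c(msg, "hemisphere must be 'L'/'R' per parcel")
  if (length(object@areaWeight) != n || any(object@areaWeight <= 0) ||
      !.near(sum(object@areaWeight), 1, 1e-9))
    msg <- c(msg, "area weights must be positive and sum to 1 (tol 1e-9)")
  if (length(msg)) msg else TRUE
})

#' FeatureTable: subjects x parcels x features
#'
#' The pipeline's raw input: one numeric value per subject, parcel and named
#' morphometric feature (defaults are the eight neonatal cortical features
#' CT, MC, MI, SA, FA, MD, NDI, ODI). No missing values are allowed.
#'
#' @slot values 3-way numeric array, dim subjects x parcels x features, with
#'   complete dimnames.
#' @slot zscored logical; \code{TRUE} after \code{\link{zscoreFeatures}}.
#'
#' @export
setClass("FeatureTable",
  representation(values = "array", zscored = "logical")
)

setValidity("FeatureTable", function(object) {
  v <- object@values
  msg <- character()
  if (length(dim(v)) != 3L)
    return("values must be a 3-way array (subjects x parcels x features)")
  if (anyNA(v)) msg <- c(msg, "missing values are not allowed")
  if (dim(v)[2] < 3L) msg <- c(msg, "need at least 3 parcels")
  if (dim(v)[3] < 3L) msg <- c(msg, "need at least 3 features")
  dn <- dimnames(v)
  if (is.null(dn) || any(vapply(dn, is.null, logical(1))))
    msg <- c(msg, "values must carry complete dimnames")
  if (length(msg)) msg else TRUE
})

#' SimilarityMatrix: an inter-regional similarity network
#'
#' A symmetric parcels x parcels matrix. \code{kind} records provenance:
#' a per-subject MSN, a group-average MSN, a single-feature structural
#' covariance network (SCN), or a matrix of edgewise age correlations.
#' MSN/SCN kinds have unit diagonal and off-diagonal entries in [-1, 1].
#'
#' @slot parcels integer parcel ids (row/column order).
#' @slot values numeric matrix.
#' @slot kind one of \code{subject_msn}, \code{group_msn}, \code{scn},
#'   \code{edge_age}.
#'
#' @export
setClass("SimilarityMatrix",
  representation(parcels = "integer", values = "matrix", kind = "character")
)

setValidity("SimilarityMatrix", function(object) {
  v <- object@values
  n <- length(object@parcels)
  msg <- character()
  if (!identical(dim(v), c(n, n)))
    return("matrix dimension must match parcel count")
  if (!object@kind %in% c("subject_msn", "group_msn", "scn", "edge_age"))
    msg <- c(msg, "unknown kind")
  if (max(abs(v - t(v))) > 1e-12)
    msg <- c(msg, "matrix must be symmetric (tol 1e-12)")
  if (object@kind %in% c("subject_msn", "group_msn", "scn")) {
    off <- v[upper.tri(v)]
    if (length(off) && (min(off) < -1 - 1e-12 || max(off) > 1 + 1e-12))
      msg <- c(msg, "off-diagonal entries must lie in [-1, 1]")
    if (any(abs(diag(v) - 1) > 1e-12))
      msg <- c(msg, "diagonal must be 1 for msn/scn kinds")
  }
  if (length(msg)) msg else TRUE
})

#' Partition: integer cluster labels over parcels
#'
#' @slot parcels integer parcel ids.
#' @slot labels integer label per parcel.
#'
#' @export
setClass("Partition",
  representation(parcels = "integer", labels = "integer")
)

setValidity("Partition", function(object) {
  if (length(object@parcels) != length(object@labels))
    return("labels must align with parcels")
  if (anyNA(object@labels)) return("every parcel must be labelled")
  TRUE
})

#' APConfig: affinity-propagation settings
#'
#' @slot preference numeric scalar, or \code{NA_real_} meaning "median of the
#'   off-diagonal similarities" (the no-prior choice used throughout).
#' @slot damping message damping factor in [0.5, 1).
#' @slot maxIter maximum message-passing iterations.
#' @slot convIter iterations of a stable exemplar set required to declare
#'   convergence.
#' @slot noiseScale magnitude of the tiny symmetric jitter used to break
#'   degenerate ties.
#' @slot seed RNG seed for the jitter.
#'
#' @export
setClass("APConfig",
  representation(
    preference = "numeric", damping = "numeric", maxIter = "integer",
    convIter = "integer", noiseScale = "numeric", seed = "integer"
  ),
  prototype(
    preference = NA_real_, damping = 0.9, maxIter = 1000L,
    convIter = 100L, noiseScale = 1e-12, seed = 1L
  )
)

setValidity("APConfig", function(object) {
  msg <- character()
  if (object@damping < 0.5 || object@damping >= 1)
    msg <- c(msg, "damping must lie in [0.5, 1)")
  if (object@convIter < 1L || object@maxIter < object@convIter)
    msg <- c(msg, "need maxIter >= convIter >= 1")
  if (object@noiseScale < 0) msg <- c(msg, "noiseScale must be >= 0")
  if (length(msg)) msg else TRUE
})

#' APResult: an affinity-propagation clustering solution
#'
#' @slot partition the label assignment as a \linkS4class{Partition}.
#' @slot exemplars integer parcel ids of the chosen exemplars, one per
#'   cluster, each carrying its own cluster label.
#' @slot k number of clusters.
#' @slot preference the resolved scalar preference used on the diagonal.
#' @slot netSimilarity sum of similarities to assigned exemplars plus the
#'   preference of each exemplar (the quantity the algorithm maximises).
#' @slot iterations message-passing iterations performed.
#' @slot converged logical convergence flag.
#'
#' @export
setClass("APResult",
  representation(
    partition = "Partition", exemplars = "integer", k = "integer",
    preference = "numeric", netSimilarity = "numeric",
    iterations = "integer", converged = "logical"
  )
)

setValidity("APResult", function(object) {
  lab <- object@partition@labels
  ex <- object@exemplars
  msg <- character()
  if (object@k != length(ex) || object@k != length(unique(lab)))
    msg <- c(msg, "k must equal the number of exemplars and distinct labels")
  idx <- match(ex, object@partition@parcels)
  if (anyNA(idx) || !identical(sort(unique(lab)), sort(lab[idx])))
    msg <- c(msg, "each exemplar must carry its own cluster label")
  if (length(msg)) msg else TRUE
})

#' CoincidenceMatrix: bootstrap co-assignment frequencies
#'
#' Entry (i, j) is the fraction of bootstrap clusterings in which parcels i
#' and j fell in the same cluster.
#'
#' @slot parcels integer parcel ids.
#' @slot values symmetric numeric matrix with entries in [0, 1], unit
#'   diagonal.
#' @slot nIterations number of bootstrap iterations.
#'
#' @export
setClass("CoincidenceMatrix",
  representation(parcels = "integer", values = "matrix", nIterations = "integer")
)

setValidity("CoincidenceMatrix", function(object) {
  v <- object@values
  n <- length(object@parcels)
  if (!identical(dim(v), c(n, n))) return("dimension mismatch")
  msg <- character()
  if (max(abs(v - t(v))) > 1e-12) msg <- c(msg, "matrix must be symmetric")
  if (min(v) < 0 || max(v) > 1) msg <- c(msg, "entries must lie in [0, 1]")
  if (any(diag(v) != 1)) msg <- c(msg, "diagonal must be 1")
  if (length(msg)) msg else TRUE
})

#' SpinTestResult: spherical spin-permutation test outcome
#'
#' @slot observed observed normalized variation of information.
#' @slot nullStats NVI values over rotated nulls.
#' @slot pValue permutation p, add-one convention.
#' @slot nPerm number of rotations.
#' @slot seed RNG seed.
#' @slot countDeviation per-permutation fraction of parcels whose label
#'   multiset changed under the many-to-one nearest-centroid mapping.
#'
#' @export
setClass("SpinTestResult",
  representation(
    observed = "numeric", nullStats = "numeric", pValue = "numeric",
    nPerm = "integer", seed = "integer", countDeviation = "numeric"
  )
)

setValidity("SpinTestResult", function(object) {
  if (object@pValue <= 0 || object@pValue > 1) return("p must lie in (0, 1]")
  expect <- (1 + sum(object@nullStats <= object@observed)) / (1 + object@nPerm)
  if (abs(object@pValue - expect) > 1e-12)
    return("p must follow the add-one permutation convention")
  TRUE
})

#' CohortConfig: parameters of the synthetic cohort generator
#'
#' Encodes the generative stand-in for a term-born neonatal imaging cohort:
#' modular mean feature profiles, a linear age effect per feature modulated
#' along a spatial (posterior-anterior) axis, an additive sex effect, and
#' iid Gaussian residual noise.
#'
#' @slot nSubjects number of subjects.
#' @slot nParcels number of parcels (must match the scheme used).
#' @slot nModules number of planted modules K.
#' @slot featureNames ordered feature names (default the eight cortical
#'   features CT, MC, MI, SA, FA, MD, NDI, ODI).
#' @slot moduleProfiles K x F matrix of module means in feature space.
#' @slot ageRangeWeeks length-2 numeric, postmenstrual age range in weeks.
#' @slot ageSlopes per-feature change per week of age.
#' @slot ageGradientAxis 3-vector; age effects scale with
#'   \code{(1 + <centroid, axis>)/2}.
#' @slot sexEffects per-feature additive shift in males.
#' @slot noiseSd residual standard deviation.
#' @slot seed RNG seed.
#'
#' @export
setClass("CohortConfig",
  representation(
    nSubjects = "integer", nParcels = "integer", nModules = "integer",
    featureNames = "character", moduleProfiles = "matrix",
    ageRangeWeeks = "numeric", ageSlopes = "numeric",
    ageGradientAxis = "numeric", sexEffects = "numeric",
    noiseSd = "numeric", seed = "integer"
  )
)

setValidity("CohortConfig", function(object) {
  K <- object@nModules
  f <- length(object@featureNames)
  msg <- character()
  if (K > object@nParcels) msg <- c(msg, "need K <= nParcels")
  if (f < 3L) msg <- c(msg, "need at least 3 features")
  if (!identical(dim(object@moduleProfiles), c(K, f)))
    msg <- c(msg, "moduleProfiles must be K x F")
  if (length(object@ageRangeWeeks) != 2L ||
      diff(object@ageRangeWeeks) < 0)
    msg <- c(msg, "ageRangeWeeks must be an interval")
  if (length(object@ageSlopes) != f || length(object@sexEffects) != f)
    msg <- c(msg, "ageSlopes and sexEffects must have one entry per feature")
  if (length(object@ageGradientAxis) != 3L)
    msg <- c(msg, "ageGradientAxis must be a 3-vector")
  if (object@noiseSd <= 0) msg <- c(msg, "noiseSd must be > 0")
  if (length(msg)) msg else TRUE
})

#' GroundTruth: the planted structure of a synthetic cohort
#'
#' @slot modulePartition the planted module labels.
#' @slot config echo of the generating \linkS4class{CohortConfig}.
#'
#' @export
setClass("GroundTruth",
  representation(modulePartition = "Partition", config = "CohortConfig")
)

setValidity("GroundTruth", function(object) {
  lab <- object@modulePartition@labels
  K <- object@config@nModules
  if (length(unique(lab)) != K)
    return("module partition must use exactly K non-empty labels")
  TRUE
})

## ---- accessors ----

#' @rdname parcelIds
#' @export
setMethod("parcelIds", "ParcelScheme", function(x) x@parcelId)
#' @rdname parcelIds
#' @export
setMethod("parcelIds", "SimilarityMatrix", function(x) x@parcels)
#' @rdname parcelIds
#' @export
setMethod("parcelIds", "Partition", function(x) x@parcels)
#' @rdname parcelIds
#' @export
setMethod("parcelIds", "CoincidenceMatrix", function(x) x@parcels)
#' @rdname parcelIds
#' @export
setMethod("parcelIds", "FeatureTable", function(x)
  as.integer(dimnames(x@values)[[2]]))

#' @rdname nParcels
#' @export
setMethod("nParcels", "ParcelScheme", function(x) length(x@parcelId))
#' @rdname nParcels
#' @export
setMethod("nParcels", "SimilarityMatrix", function(x) length(x@parcels))
#' @rdname nParcels
#' @export
setMethod("nParcels", "Partition", function(x) length(x@parcels))
#' @rdname nParcels
#' @export
setMethod("nParcels", "FeatureTable", function(x) dim(x@values)[2])

#' @rdname membership
#' @export
setMethod("membership", "Partition", function(x) {
  stats::setNames(x@labels, x@parcels)
})
#' @rdname membership
#' @export
setMethod("membership", "APResult", function(x) membership(x@partition))

#' @rdname nClusters
#' @export
setMethod("nClusters", "Partition", function(x) length(unique(x@labels)))
#' @rdname nClusters
#' @export
setMethod("nClusters", "APResult", function(x) x@k)

#' @rdname simValues
#' @export
setMethod("simValues", "SimilarityMatrix", function(x) {
  v <- x@values
  dimnames(v) <- list(x@parcels, x@parcels)
  v
})
#' @rdname simValues
#' @export
setMethod("simValues", "CoincidenceMatrix", function(x) {
  v <- x@values
  dimnames(v) <- list(x@parcels, x@parcels)
  v
})

#' @rdname matrixKind
#' @export
setMethod("matrixKind", "SimilarityMatrix", function(x) x@kind)

#' @rdname centroids
#' @export
setMethod("centroids", "ParcelScheme", function(x) x@centroids)
#' @rdname areaWeights
#' @export
setMethod("areaWeights", "ParcelScheme", function(x) x@areaWeight)
#' @rdname hemispheres
#' @export
setMethod("hemispheres", "ParcelScheme", function(x) x@hemisphere)

#' @rdname exemplars
#' @export
setMethod("exemplars", "APResult", function(x) x@exemplars)

#' @rdname subjectIds
#' @export
setMethod("subjectIds", "FeatureTable", function(x) dimnames(x@values)[[1]])
#' @rdname featureNames
#' @export
setMethod("featureNames", "FeatureTable", function(x) dimnames(x@values)[[3]])
#' @rdname featureValues
#' @export
setMethod("featureValues", "FeatureTable", function(x) x@values)

## ---- show methods ----

setMethod("show", "ParcelScheme", function(object) {
  cat("ParcelScheme with", nParcels(object), "parcels",
      sprintf("(%d L / %d R)\n", sum(object@hemisphere == "L"),
              sum(object@hemisphere == "R")))
  cat("  area weight CV:",
      round(stats::sd(object@areaWeight) / mean(object@areaWeight), 3), "\n")
})

setMethod("show", "FeatureTable", function(object) {
  d <- dim(object@values)
  cat(sprintf("FeatureTable: %d subjects x %d parcels x %d features%s\n",
              d[1], d[2], d[3], if (object@zscored) " (z-scored)" else ""))
  cat("  features:", paste(featureNames(object), collapse = ", "), "\n")
})

setMethod("show", "SimilarityMatrix", function(object) {
  cat(sprintf("SimilarityMatrix [%s]: %d x %d\n", object@kind,
              nParcels(object), nParcels(object)))
  off <- object@values[upper.tri(object@values)]
  cat(sprintf("  off-diagonal range [%.3f, %.3f], mean %.3f\n",
              min(off), max(off), mean(off)))
})

setMethod("show", "Partition", function(object) {
  tab <- table(object@labels)
  cat(sprintf("Partition of %d parcels into %d clusters (sizes %s)\n",
              nParcels(object), length(tab),
              paste(as.integer(tab), collapse = ", ")))
})

setMethod("show", "APResult", function(object) {
  cat(sprintf(
    "APResult: k = %d, net similarity %.4f, %d iterations (%s)\n",
    object@k, object@netSimilarity, object@iterations,
    if (object@converged) "converged" else "NOT converged"))
  cat("  exemplars:", paste(object@exemplars, collapse = ", "), "\n")
})

setMethod("show", "SpinTestResult", function(object) {
  cat(sprintf(
    "Spin test: observed NVI %.4f vs %d rotated nulls (null range %.3f-%.3f)\n",
    object@observed, object@nPerm, min(object@nullStats),
    max(object@nullStats)))
  cat(sprintf("  p = %.4g\n", object@pValue))
})

setMethod("show", "CohortConfig", function(object) {
  cat(sprintf(
    "CohortConfig: %d subjects, %d parcels, %d modules, %d features\n",
    object@nSubjects, object@nParcels, object@nModules,
    length(object@featureNames)))
  cat(sprintf("  age %.2f-%.2f weeks, noise sd %.3g, seed %d\n",
              object@ageRangeWeeks[1], object@ageRangeWeeks[2],
              object@noiseSd, object@seed))
})

setMethod("show", "CoincidenceMatrix", function(object) {
  cat(sprintf("CoincidenceMatrix: %d parcels, %d bootstrap iterations\n",
              length(object@parcels), object@nIterations))
})

## ---- small constructors used across the package ----

#' Build a Partition from a label vector
#'
#' @param labels integer-like labels, one per parcel.
#' @param parcels parcel ids; defaults to \code{1..n}.
#' @return a \linkS4class{Partition}.
#' @export
newPartition <- function(labels, parcels = seq_along(labels)) {
  new("Partition", parcels = as.integer(parcels), labels = as.integer(labels))
}

newSimilarityMatrix <- function(values, kind, parcels = seq_len(nrow(values))) {
  values <- (values + t(values)) / 2  # kill last-bit asymmetry
  new("SimilarityMatrix", parcels = as.integer(parcels),
      values = unname(values), kind = kind)
}
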
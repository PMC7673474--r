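NULL

#' Parcel identifiers of an object
#'
#' @param x a \linkS4class{ParcelScheme}, \linkS4class{SimilarityMatrix},
#'   \linkS4class{Partition}, \linkS4class{FeatureTable} or
#'   \linkS4class{CoincidenceMatrix}.
#' @return integer vector of parcel ids.
#' @export
setGeneric("parcelIds", function(x) standardGeneric("parcelIds"))

#' Number of parcels
#' @param x an object carrying a parcel dimension.
#' @return integer scalar.
#' @export
setGeneric("nParcels", function(x) standardGeneric("nParcels"))

#' Cluster membership vector
#'
#' Integer label per parcel, in parcel order.
#' @param x a \linkS4class{Partition} or \linkS4class{APResult}.
#' @return named integer vector.
#' @export
setGeneric("membership", function(x) standardGeneric("membership"))

#' Number of clusters in a partition
#' @param x a \linkS4class{Partition} or \linkS4class{APResult}.
#' @return integer scalar.
#' @export
setGeneric("nClusters", function(x) standardGeneric("nClusters"))

#' Numeric matrix payload of a similarity-like object
#' @param x a \linkS4class{SimilarityMatrix} or \linkS4class{CoincidenceMatrix}.
#' @return numeric matrix with parcel ids as dimnames.
#' @export
setGeneric("simValues", function(x) standardGeneric("simValues"))

#' Kind label of a similarity matrix
#' @param x a \linkS4class{SimilarityMatrix}.
#' @return one of \code{"subject_msn"}, \code{"group_msn"}, \code{"scn"},
#'   \code{"edge_age"}.
#' @export
setGeneric("matrixKind", function(x) standardGeneric("matrixKind"))

#' Parcel centroids on the unit sphere
#' @param x a \linkS4class{ParcelScheme}.
#' @return n x 3 numeric matrix.
#' @export
setGeneric("centroids", function(x) standardGeneric("centroids"))

#' Relative parcel areas
#' @param x a \linkS4class{ParcelScheme}.
#' @return numeric vector summing to 1.
#' @export
setGeneric("areaWeights", function(x) standardGeneric("areaWeights"))

#' Hemisphere labels
#' @param x a \linkS4class{ParcelScheme}.
#' @return character vector of \code{"L"}/\code{"R"}.
#' @export
setGeneric("hemispheres", function(x) standardGeneric("hemispheres"))

#' Exemplar parcels of an affinity-propagation solution
#' @param x an \linkS4class{APResult}.
#' @return integer vector of exemplar parcel ids, one per cluster.
#' @export
setGeneric("exemplars", function(x) standardGeneric("exemplars"))

#' Subject identifiers
#' @param x a \linkS4class{FeatureTable}.
#' @return character vector.
#' @export
setGeneric("subjectIds", function(x) standardGeneric("subjectIds"))

#' Feature names
#' @param x a \linkS4class{FeatureTable}.
#' @return character vector.
#' @export
setGeneric("featureNames", function(x) standardGeneric("featureNames"))

#' Raw subjects x parcels x features array
#' @param x a \linkS4class{FeatureTable}.
#' @return 3-way numeric array.
#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))
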
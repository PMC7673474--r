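#' @include AllClasses.R
NULL

# On-disk cohort layout: scheme.tsv, features.tsv (long), meta.tsv,
# truth.json. Plain TSV/JSON so cohorts are diffable and portable.

#' Write a synthetic cohort to a directory
#'
#' @param cohort list as returned by \code{\link{simulateCohort}}.
#' @param scheme the \linkS4class{ParcelScheme} the cohort lives on.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeCohort <- function(cohort, scheme, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeScheme(scheme, file.path(dir, "scheme.tsv"))
  writeFeatureTable(cohort$features, file.path(dir, "features.tsv"))
  utils::write.table(cohort$meta, file.path(dir, "meta.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  truth <- cohort$truth
  cfg <- truth@config
  jsonlite::write_json(list(
    labels = truth@modulePartition@labels,
    parcels = truth@modulePartition@parcels,
    config = list(
      n_subjects = cfg@nSubjects, n_parcels = cfg@nParcels,
      n_modules = cfg@nModules, feature_names = cfg@featureNames,
      module_profiles = cfg@moduleProfiles,
      age_range_weeks = cfg@ageRangeWeeks, age_slopes = cfg@ageSlopes,
      age_gradient_axis = cfg@ageGradientAxis,
      sex_effects = cfg@sexEffects, noise_sd = cfg@noiseSd,
      seed = cfg@seed)),
    file.path(dir, "truth.json"), digits = NA, auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname writeCohort
#' @param path file path.
#' @export
writeScheme <- function(scheme, path) {
  cen <- centroids(scheme)
  df <- data.frame(parcel_id = parcelIds(scheme),
                   x = cen[, 1], y = cen[, 2], z = cen[, 3],
                   hemisphere = hemispheres(scheme),
                   area_weight = areaWeights(scheme))
  utils::write.table(format(df, digits = 17, scientific = FALSE,
                            trim = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCohort
#' @param table a \linkS4class{FeatureTable}.
#' @export
writeFeatureTable <- function(table, path) {
  v <- featureValues(table)
  d <- dim(v)
  long <- data.frame(
    subject_id = rep(dimnames(v)[[1]], times = d[2] * d[3]),
    parcel_id = rep(rep(dimnames(v)[[2]], each = d[1]), times = d[3]),
    feature = rep(dimnames(v)[[3]], each = d[1] * d[2]),
    value = as.vector(v))
  utils::write.table(format(long, digits = 17, scientific = FALSE,
                            trim = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a cohort directory
#'
#' @param dir directory written by \code{\link{writeCohort}}.
#' @return list with \code{scheme}, \code{features}, \code{meta},
#'   \code{truthPartition} (NULL when truth.json is absent).
#' @export
readCohort <- function(dir) {
  scheme <- readScheme(file.path(dir, "scheme.tsv"))
  features <- readFeatureTable(file.path(dir, "features.tsv"))
  meta <- utils::read.table(file.path(dir, "meta.tsv"), sep = "\t",
                            header = TRUE, stringsAsFactors = FALSE)
  truthPath <- file.path(dir, "truth.json")
  truth <- NULL
  if (file.exists(truthPath)) {
    tj <- jsonlite::read_json(truthPath, simplifyVector = TRUE)
    truth <- newPartition(tj$labels, tj$parcels)
  }
  list(scheme = scheme, features = features, meta = meta,
       truthPartition = truth)
}

#' @rdname readCohort
#' @param path file path.
#' @export
readScheme <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("parcel_id", "x", "y", "z", "hemisphere", "area_weight")
  if (!all(need %in% names(df)))
    stop("scheme file must have columns ", paste(need, collapse = ", "))
  df <- df[order(df$parcel_id), ]
  cen <- as.matrix(df[, c("x", "y", "z")])
  cen <- cen / sqrt(rowSums(cen^2))  # renormalise text round-off
  dimnames(cen) <- NULL
  new("ParcelScheme", parcelId = as.integer(df$parcel_id),
      centroids = cen, hemisphere = df$hemisphere,
      areaWeight = df$area_weight / sum(df$area_weight))
}

#' @rdname readCohort
#' @export
readFeatureTable <- function(path) {
  long <- utils::read.table(path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
  subs <- unique(long$subject_id)
  parc <- sort(unique(as.integer(long$parcel_id)))
  feats <- unique(long$feature)
  v <- array(NA_real_, dim = c(length(subs), length(parc), length(feats)),
             dimnames = list(subs, parc, feats))
  v[cbind(match(long$subject_id, subs),
          match(as.integer(long$parcel_id), parc),
          match(long$feature, feats))] <- long$value
  if (anyNA(v)) stop("feature table has missing cells")
  new("FeatureTable", values = v, zscored = FALSE)
}

#' Write a similarity matrix as TSV
#'
#' Full double precision, parcel ids as header row and first column.
#'
#' @param m a \linkS4class{SimilarityMatrix}.
#' @param path file path.
#' @export
writeSimilarityMatrix <- function(m, path) {
  v <- simValues(m)
  df <- data.frame(parcel_id = rownames(v),
                   format(as.data.frame(v), digits = 17, trim = TRUE))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a partition as TSV
#'
#' @param partition a \linkS4class{Partition}.
#' @param path file path.
#' @param exemplarIds optional exemplar parcel ids (adds an is_exemplar
#'   column).
#' @export
writePartition <- function(partition, path, exemplarIds = integer()) {
  df <- data.frame(parcel_id = partition@parcels,
                   label = partition@labels,
                   is_exemplar = partition@parcels %in% exemplarIds)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Validate a cohort directory
#'
#' Checks the type invariants of the on-disk cohort: unit-norm centroids,
#' contiguous parcel ids, complete feature cells, subject alignment
#' between features and metadata, ages within range. Returns a report
#' rather than stopping, so callers can surface all problems at once.
#'
#' @param dir cohort directory.
#' @return list with logical \code{pass} and character
#'   \code{problems}.
#' @export
validateInputs <- function(dir) {
  problems <- character()
  note <- function(msg) problems <<- c(problems, msg)
  schemeDf <- tryCatch(
    utils::read.table(file.path(dir, "scheme.tsv"), sep = "\t",
                      header = TRUE, stringsAsFactors = FALSE),
    error = function(e) { note(paste("scheme.tsv:", conditionMessage(e))); NULL })
  if (!is.null(schemeDf)) {
    nrm <- sqrt(schemeDf$x^2 + schemeDf$y^2 + schemeDf$z^2)
    bad <- which(abs(nrm - 1) > 1e-6)
    for (b in bad)
      note(sprintf("scheme.tsv: parcel %d centroid norm %.4f (expected 1)",
                   schemeDf$parcel_id[b], nrm[b]))
    if (!identical(sort(schemeDf$parcel_id), seq_len(nrow(schemeDf))))
      note("scheme.tsv: parcel ids are not contiguous 1..n")
  }
  long <- tryCatch(
    utils::read.table(file.path(dir, "features.tsv"), sep = "\t",
                      header = TRUE, stringsAsFactors = FALSE),
    error = function(e) { note(paste("features.tsv:", conditionMessage(e))); NULL })
  meta <- tryCatch(
    utils::read.table(file.path(dir, "meta.tsv"), sep = "\t",
                      header = TRUE, stringsAsFactors = FALSE),
    error = function(e) { note(paste("meta.tsv:", conditionMessage(e))); NULL })
  if (!is.null(long)) {
    subs <- unique(long$subject_id)
    parc <- unique(long$parcel_id)
    feats <- unique(long$feature)
    cells <- table(long$subject_id, long$feature)
    miss <- which(cells != length(parc), arr.ind = TRUE)
    if (nrow(miss))
      for (r in seq_len(min(nrow(miss), 10)))
        note(sprintf(
          "features.tsv: subject %s feature %s has %d of %d parcel values",
          rownames(cells)[miss[r, 1]], colnames(cells)[miss[r, 2]],
          cells[miss[r, 1], miss[r, 2]], length(parc)))
    if (anyNA(long$value)) note("features.tsv: missing values present")
    if (!is.null(meta) && !setequal(subs, meta$subject_id))
      note("features.tsv/meta.tsv: subject sets differ")
  }
  if (!is.null(meta)) {
    if (!all(meta$sex %in% c("M", "F")))
      note("meta.tsv: sex must be M or F")
  }
  list(pass = length(problems) == 0, problems = problems)
}
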
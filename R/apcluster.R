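#' @include AllClasses.R
NULL

#' Affinity-propagation configuration constructor
#'
#' @param preference numeric scalar, or \code{"median"} / \code{NA} to use
#'   the median of the off-diagonal similarities.
#' @param damping message damping in [0.5, 1).
#' @param maxIter,convIter iteration budget and stable-exemplar window.
#' @param noiseScale tie-breaking jitter magnitude.
#' @param seed jitter RNG seed.
#' @return an \linkS4class{APConfig}.
#' @export
apConfig <- function(preference = "median", damping = 0.9, maxIter = 1000L,
                     convIter = 100L, noiseScale = 1e-12, seed = 1L) {
  pref <- if (identical(preference, "median")) NA_real_ else as.numeric(preference)
  new("APConfig", preference = pref, damping = damping,
      maxIter = as.integer(maxIter), convIter = as.integer(convIter),
      noiseScale = noiseScale, seed = as.integer(seed))
}

#' Median preference of a similarity matrix
#'
#' The "no prior assumption" preference: the median of the strict
#' upper-triangle (off-diagonal) similarities, so every node is considered
#' an equally plausible exemplar.
#'
#' @param S a \linkS4class{SimilarityMatrix} (or plain square matrix).
#' @return numeric scalar.
#' @export
medianPreference <- function(S) {
  v <- if (is(S, "SimilarityMatrix")) S@values else S
  if (nrow(v) < 2) stop("need at least 2 parcels")
  stats::median(v[upper.tri(v)])
}

# Resolve preference + jitter; returns the working similarity matrix with
# the preference on the diagonal.
.apPrepare <- function(v, config) {
  pref <- config@preference
  if (is.na(pref)) pref <- medianPreference(v)
  n <- nrow(v)
  S <- v
  diag(S) <- pref
  if (config@noiseScale > 0) {
    jit <- withSeed(config@seed, matrix(stats::runif(n * n) - 0.5, n, n))
    jit <- (jit + t(jit)) * config@noiseScale
    S <- S + jit
  }
  list(S = S, preference = pref)
}

#' Affinity-propagation clustering
#'
#' Frey-Dueck message passing on a similarity matrix: responsibilities
#' \eqn{r(i,k) \leftarrow s(i,k) - \max_{k' \ne k}[a(i,k') + s(i,k')]} and
#' availabilities
#' \eqn{a(i,k) \leftarrow \min(0, r(k,k) + \sum_{i' \notin \{i,k\}} \max(0, r(i',k)))}
#' (self-availability \eqn{a(k,k) = \sum_{i' \ne k} \max(0, r(i',k))}),
#' both damped. Exemplars are the points with \eqn{r(k,k) + a(k,k) > 0}
#' at convergence; every other point joins the exemplar with the highest
#' similarity. The number of clusters is controlled by the shared
#' preference value placed on the diagonal, not given in advance.
#'
#' A tiny seeded symmetric jitter breaks degenerate ties. Non-convergence
#' within \code{maxIter} returns the current solution with
#' \code{converged = FALSE} and a warning.
#'
#' @param S a \linkS4class{SimilarityMatrix} or plain square numeric
#'   matrix.
#' @param config an \linkS4class{APConfig}.
#' @return an \linkS4class{APResult}.
#' @references Frey BJ, Dueck D (2007) Clustering by passing messages
#'   between data points. Science 315:972-976.
#' @export
affinityPropagation <- function(S, config = apConfig()) {
  validObject(config)
  parcels <- if (is(S, "SimilarityMatrix")) S@parcels else
    seq_len(nrow(as.matrix(S)))
  v <- if (is(S, "SimilarityMatrix")) S@values else as.matrix(S)
  if (nrow(v) != ncol(v)) stop("similarity matrix must be square")
  n <- nrow(v)
  if (n == 1L) {
    pref <- if (is.na(config@preference)) v[1, 1] else config@preference
    return(new("APResult",
               partition = newPartition(1L, parcels),
               exemplars = parcels[1], k = 1L,
               preference = pref, netSimilarity = pref,
               iterations = 0L, converged = TRUE))
  }
  prep <- .apPrepare(v, config)
  Sw <- prep$S
  lam <- config@damping
  R <- A <- matrix(0, n, n)
  diagIdx <- cbind(seq_len(n), seq_len(n))
  exemplarRun <- 0L
  lastEx <- rep(FALSE, n)
  it <- 0L
  converged <- FALSE
  while (it < config@maxIter) {
    it <- it + 1L
    ## responsibilities
    AS <- A + Sw
    i1 <- max.col(AS, ties.method = "first")
    m1 <- AS[cbind(seq_len(n), i1)]
    AS[cbind(seq_len(n), i1)] <- -Inf
    m2 <- AS[cbind(seq_len(n), max.col(AS, ties.method = "first"))]
    Rnew <- Sw - m1
    Rnew[cbind(seq_len(n), i1)] <- Sw[cbind(seq_len(n), i1)] - m2
    R <- lam * R + (1 - lam) * Rnew
    ## availabilities
    Rp <- pmax(R, 0)
    Rp[diagIdx] <- R[diagIdx]
    cs <- colSums(Rp)
    Anew <- rep(cs, each = n) - Rp
    dA <- Anew[diagIdx]
    Anew <- pmin(Anew, 0)
    Anew[diagIdx] <- dA
    A <- lam * A + (1 - lam) * Anew
    ## convergence on the exemplar indicator
    ex <- (R[diagIdx] + A[diagIdx]) > 0
    if (any(ex) && identical(ex, lastEx)) {
      exemplarRun <- exemplarRun + 1L
      if (exemplarRun >= config@convIter) { converged <- TRUE; break }
    } else {
      exemplarRun <- 0L
    }
    lastEx <- ex
  }
  exIdx <- which((R[diagIdx] + A[diagIdx]) > 0)
  if (!length(exIdx)) exIdx <- which.max(R[diagIdx] + A[diagIdx])
  if (!converged)
    warning(sprintf(
      "affinity propagation did not converge in %d iterations (k = %d)",
      it, length(exIdx)))
  ## assignment: nearest exemplar by (jittered) similarity, then the
  ## standard refinement pass (re-pick each cluster's best exemplar and
  ## reassign until stable), as in the reference implementation
  assign <- exIdx[max.col(Sw[, exIdx, drop = FALSE], ties.method = "first")]
  assign[exIdx] <- exIdx
  for (pass in 1:20) {
    newEx <- vapply(exIdx, function(k) {
      members <- which(assign == k)
      scores <- vapply(members, function(j)
        prep$preference + sum(Sw[members[members != j], j]), numeric(1))
      members[which.max(scores)]
    }, integer(1))
    newEx <- sort(unique(newEx))
    newAssign <- newEx[max.col(Sw[, newEx, drop = FALSE],
                               ties.method = "first")]
    newAssign[newEx] <- newEx
    if (identical(newEx, exIdx) && identical(newAssign, assign)) break
    exIdx <- newEx
    assign <- newAssign
  }
  labels <- match(assign, exIdx)
  net <- sum(Sw[cbind(seq_len(n), assign)][-exIdx]) +
    length(exIdx) * prep$preference
  new("APResult",
      partition = newPartition(labels, parcels),
      exemplars = parcels[exIdx], k = length(exIdx),
      preference = prep$preference,
      netSimilarity = net, iterations = it, converged = converged)
}

#' Net similarity of an exemplar assignment
#'
#' The objective affinity propagation maximises: similarity of every
#' non-exemplar to its exemplar plus the preference for each exemplar.
#' Exposed for oracle-style checks against exhaustive enumeration.
#'
#' @param v square similarity matrix (diagonal ignored).
#' @param exIdx indices of the exemplar set.
#' @param preference shared preference scalar.
#' @return numeric scalar.
#' @export
netSimilarityOf <- function(v, exIdx, preference) {
  n <- nrow(v)
  best <- apply(v[, exIdx, drop = FALSE], 1, max)
  best[exIdx] <- 0
  sum(best[-exIdx]) + length(exIdx) * preference
}

#' Affinity propagation with a fixed number of clusters
#'
#' Bisection search over the shared preference: the achieved number of
#' exemplars is non-decreasing in the preference, so the scalar is bisected
#' on \code{[min(s) - range(s), max(s)]} until affinity propagation returns
#' exactly \code{kTarget} clusters.
#'
#' @param S a \linkS4class{SimilarityMatrix} or square matrix.
#' @param kTarget desired cluster count, \code{1 <= kTarget <= n}.
#' @param config an \linkS4class{APConfig}; its preference field is
#'   ignored (the search owns it).
#' @param maxSteps bisection budget.
#' @return an \linkS4class{APResult} with \code{k == kTarget}.
#' @export
clusterFixedK <- function(S, kTarget, config = apConfig(), maxSteps = 50L) {
  v <- if (is(S, "SimilarityMatrix")) S@values else as.matrix(S)
  n <- nrow(v)
  if (kTarget < 1 || kTarget > n) stop("kTarget must lie in [1, n]")
  if (n == 1L) return(affinityPropagation(S, config))
  off <- v[upper.tri(v)]
  rng <- max(max(off) - min(off), 1e-3)
  lo <- min(off) - rng - 1e-6
  hi <- max(off) + 1e-6
  probe <- function(p) {
    cfg <- config
    cfg@preference <- p
    suppressWarnings(affinityPropagation(S, cfg))
  }
  resLo <- probe(lo); resHi <- probe(hi)
  if (resLo@k == kTarget) return(resLo)
  if (resHi@k == kTarget) return(resHi)
  # widen until the endpoints bracket the target (k is non-decreasing in
  # the preference, but the nominal interval need not reach k = 1)
  widen <- 0L
  while (resLo@k > kTarget && widen < 30L) {
    widen <- widen + 1L
    lo <- lo - rng * 2^widen
    resLo <- probe(lo)
    if (resLo@k == kTarget) return(resLo)
  }
  while (resHi@k < kTarget && widen < 60L) {
    widen <- widen + 1L
    hi <- hi + rng * 2^widen
    resHi <- probe(hi)
    if (resHi@k == kTarget) return(resHi)
  }
  seen <- c(resLo@k, resHi@k)
  for (step in seq_len(maxSteps)) {
    mid <- (lo + hi) / 2
    res <- probe(mid)
    seen <- c(seen, res@k)
    if (res@k == kTarget) return(res)
    if (res@k < kTarget) lo <- mid else hi <- mid
  }
  below <- seen[seen < kTarget]; above <- seen[seen > kTarget]
  stop(sprintf(
    "preference search failed to reach k = %d (nearest achieved: %s, %s)",
    kTarget,
    if (length(below)) max(below) else "none",
    if (length(above)) min(above) else "none"))
}

#' Bootstrap stability of the clustering solution
#'
#' Repeatedly draws \code{drawSize} subjects without replacement, averages
#' their similarity matrices, clusters the average, and counts how often
#' each parcel pair lands in the same cluster. High within-module and low
#' between-module coincidence indicates a stable modular solution.
#'
#' @param subjectMatrices list of per-subject
#'   \linkS4class{SimilarityMatrix}.
#' @param drawSize subjects per bootstrap draw.
#' @param iterations number of draws.
#' @param kTarget fixed cluster count, or \code{NULL} for free-k
#'   (median-preference) clustering.
#' @param config an \linkS4class{APConfig}.
#' @param seed RNG seed for the draws.
#' @return a \linkS4class{CoincidenceMatrix}.
#' @export
bootstrapStability <- function(subjectMatrices, drawSize = 20L,
                               iterations = 500L, kTarget = NULL,
                               config = apConfig(), seed = 1L) {
  if (!length(subjectMatrices)) stop("empty subject list")
  if (drawSize > length(subjectMatrices))
    stop("drawSize exceeds the number of subjects")
  p0 <- parcelIds(subjectMatrices[[1]])
  n <- length(p0)
  counts <- matrix(0, n, n)
  withSeed(stageSeed(seed, "bootstrap"), {
    for (b in seq_len(iterations)) {
      draw <- sample.int(length(subjectMatrices), drawSize)
      avg <- groupMSN(subjectMatrices[draw])
      res <- if (is.null(kTarget))
        suppressWarnings(affinityPropagation(avg, config))
      else clusterFixedK(avg, kTarget, config)
      lab <- res@partition@labels
      counts <- counts + outer(lab, lab, "==")
    }
  })
  new("CoincidenceMatrix", parcels = p0, values = counts / iterations,
      nIterations = as.integer(iterations))
}

#' Per-subject clustering consistency
#'
#' Clusters each subject's own similarity matrix at a fixed k and reports
#' the normalized variation of information against the group-level
#' partition. Subjects whose preference search fails are reported, not
#' fatal.
#'
#' @param subjectMatrices list of per-subject
#'   \linkS4class{SimilarityMatrix}.
#' @param groupPartition group-level \linkS4class{Partition}.
#' @param kTarget fixed cluster count.
#' @param config an \linkS4class{APConfig}.
#' @return data.frame with columns subject, nvi, k, converged, error.
#' @export
clusterSubjects <- function(subjectMatrices, groupPartition, kTarget = 7L,
                            config = apConfig()) {
  ids <- names(subjectMatrices)
  if (is.null(ids)) ids <- as.character(seq_along(subjectMatrices))
  rows <- lapply(seq_along(subjectMatrices), function(s) {
    res <- tryCatch(clusterFixedK(subjectMatrices[[s]], kTarget, config),
                    error = function(e) e)
    if (inherits(res, "error"))
      return(data.frame(subject = ids[s], nvi = NA_real_, k = NA_integer_,
                        converged = NA, error = conditionMessage(res),
                        stringsAsFactors = FALSE))
    data.frame(subject = ids[s],
               nvi = normalizedVI(res@partition, groupPartition),
               k = res@k, converged = res@converged, error = NA_character_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Cluster the edge-age correlation matrix
#'
#' Treats the parcels x parcels matrix of edgewise age correlations as a
#' similarity matrix and clusters it with affinity propagation, grouping
#' regions by the direction and strength of their maturation rather than
#' by morphometric similarity itself. The diagonal is ignored (replaced by
#' the preference).
#'
#' @param edgeAge a \linkS4class{SimilarityMatrix} of kind
#'   \code{edge_age}.
#' @param kTarget fixed cluster count, or \code{NULL} for free-k.
#' @param config an \linkS4class{APConfig}.
#' @return an \linkS4class{APResult}.
#' @export
clusterEdgeAgeMatrix <- function(edgeAge, kTarget = NULL,
                                 config = apConfig()) {
  if (matrixKind(edgeAge) != "edge_age")
    stop("expected a matrix of kind 'edge_age'")
  if (is.null(kTarget))
    suppressWarnings(affinityPropagation(edgeAge, config))
  else clusterFixedK(edgeAge, kTarget, config)
}
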
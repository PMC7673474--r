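#' @include AllClasses.R
NULL

#' Generate an approximately equal-area spherical parcellation
#'
#' Draws \code{nParcels} seed points uniformly on the unit sphere and
#' relaxes them with Lloyd iterations against a fixed Monte-Carlo point
#' cloud (spherical k-means): each sample point is assigned to its nearest
#' seed by great-circle distance and seeds move to the normalized mean of
#' their assigned points. Relative Voronoi areas are estimated from the
#' final point assignment.
#'
#' @param nParcels number of parcels (>= 2).
#' @param seed RNG seed; the result is a pure function of
#'   \code{(nParcels, seed)}.
#' @param nMonteCarlo size of the sample cloud used for relaxation and
#'   area estimation.
#' @param nIter Lloyd iterations.
#' @return a \linkS4class{ParcelScheme}.
#' @examples
#' sc <- makeParcellation(50, seed = 1)
#' range(sqrt(rowSums(centroids(sc)^2)))
#' @export
makeParcellation <- function(nParcels, seed = 1L, nMonteCarlo = 1e5,
                             nIter = 30L) {
  if (nParcels < 2) stop("nParcels must be >= 2")
  withSeed(stageSeed(seed, "parcellation"), {
    pts <- runifSphere(nMonteCarlo)
    cen <- runifSphere(nParcels)
    for (it in seq_len(nIter)) {
      # nearest centroid = max dot product on the sphere
      idx <- max.col(pts %*% t(cen), ties.method = "first")
      for (p in seq_len(nParcels)) {
        sel <- idx == p
        if (!any(sel)) {  # re-seed an empty cell at the loneliest point
          far <- which.min(apply(pts %*% t(cen), 1, max))
          cen[p, ] <- pts[far, ]
          next
        }
        m <- colSums(pts[sel, , drop = FALSE])
        cen[p, ] <- m / sqrt(sum(m^2))
      }
    }
    idx <- max.col(pts %*% t(cen), ties.method = "first")
    counts <- tabulate(idx, nbins = nParcels)
    w <- counts / sum(counts)
    if (any(w == 0)) stop("degenerate parcellation: empty parcel")
    new("ParcelScheme",
        parcelId = seq_len(nParcels),
        centroids = cen,
        hemisphere = ifelse(cen[, 1] < 0, "L", "R"),
        areaWeight = w)
  })
}

#' Plant spatially contiguous modules on a parcellation
#'
#' Selects K module seeds by farthest-point sampling over parcel centroids
#' and assigns every parcel to its nearest seed by great-circle distance,
#' yielding contiguous patches. With \code{mirrorSymmetric = TRUE} seeds are
#' placed in the right hemisphere and reflected through the x = 0 plane,
#' the mirrored seed sharing its partner's label, so modules are broadly
#' hemisphere-symmetric (as cortical modules tend to be).
#'
#' @param scheme a \linkS4class{ParcelScheme}.
#' @param K number of modules, \code{1 <= K <=} number of parcels.
#' @param seed RNG seed (start of the farthest-point sweep).
#' @param mirrorSymmetric logical.
#' @return a \linkS4class{Partition} with labels \code{1..K}.
#' @export
plantModules <- function(scheme, K, seed = 1L, mirrorSymmetric = FALSE) {
  n <- nParcels(scheme)
  if (K < 1 || K > n) stop("K must lie in [1, nParcels]")
  cen <- centroids(scheme)
  if (K == 1) return(newPartition(rep(1L, n)))
  if (K == n) return(newPartition(seq_len(n)))
  withSeed(stageSeed(seed, "plant-modules"), {
    pool <- if (mirrorSymmetric) which(cen[, 1] >= 0) else seq_len(n)
    if (length(pool) < K) pool <- seq_len(n)  # tiny/haphazard schemes
    seeds <- farthestPoints(cen[pool, , drop = FALSE], K)
    seedXYZ <- cen[pool[seeds], , drop = FALSE]
    if (mirrorSymmetric) {
      mirrored <- seedXYZ
      mirrored[, 1] <- -mirrored[, 1]
      seedXYZ <- rbind(seedXYZ, mirrored)
      lab <- rep(seq_len(K), 2L)
    } else {
      lab <- seq_len(K)
    }
    assign <- max.col(cen %*% t(seedXYZ), ties.method = "first")
    labels <- lab[assign]
    # guarantee every module non-empty: give each seed its nearest parcel
    for (k in seq_len(K)) {
      if (!any(labels == k)) {
        d <- cen %*% seedXYZ[k, ]
        labels[which.max(d)] <- k
      }
    }
    newPartition(labels)
  })
}

# Farthest-point sampling over rows of a centroid matrix; returns row
# indices. Random start, then greedily maximise the minimum angular
# distance to the chosen set.
farthestPoints <- function(cen, K) {
  n <- nrow(cen)
  picked <- sample.int(n, 1L)
  if (K == 1L) return(picked)
  # minimum similarity (max similarity = closest); track max-dot to set
  best <- cen %*% cen[picked, ]
  for (k in 2:K) {
    nxt <- which.min(best)
    picked <- c(picked, nxt)
    best <- pmax(best, cen %*% cen[nxt, ])
  }
  picked
}

#' Default cohort configuration
#'
#' Mirrors the statistical shape of a term-born neonatal cohort scanned
#' 37.43-44.71 weeks postmenstrual age: 241 subjects, 150 parcels, 7
#' mirror-symmetric modules, eight features. Module mean profiles are
#' mutually orthonormal in feature space (after centering) so that modules
#' are identifiable in the similarity network; age slopes follow the
#' qualitative pattern reported for this age range (SA and MI clearly
#' positive, CT/NDI/ODI mildly positive, MD negative, FA mixed via the
#' spatial gradient, MC near zero); sex effects are small shifts on frontal
#' features.
#'
#' @param nSubjects,nParcels,nModules cohort dimensions.
#' @param noiseSd residual sd per feature cell.
#' @param seed RNG seed (also seeds the profile matrix).
#' @param ageSlopes,sexEffects optional per-feature overrides.
#' @param moduleProfiles optional K x F override.
#' @return a \linkS4class{CohortConfig}.
#' @export
defaultCohortConfig <- function(nSubjects = 241L, nParcels = 150L,
                                nModules = 7L, noiseSd = 0.5, seed = 1L,
                                ageSlopes = NULL, sexEffects = NULL,
                                moduleProfiles = NULL) {
  feats <- c("CT", "MC", "MI", "SA", "FA", "MD", "NDI", "ODI")
  if (is.null(moduleProfiles))
    moduleProfiles <- orthogonalProfiles(nModules, length(feats),
                                         seed = stageSeed(seed, "profiles"),
                                         scale = sqrt(length(feats)))
  colnames(moduleProfiles) <- feats
  if (is.null(ageSlopes))
    ageSlopes <- c(CT = 0.02, MC = 0, MI = 0.05, SA = 0.05, FA = 0.02,
                   MD = -0.04, NDI = 0.02, ODI = 0.02)
  if (is.null(sexEffects))
    sexEffects <- c(CT = 0.05, MC = 0, MI = 0, SA = 0.05, FA = 0,
                    MD = 0, NDI = 0, ODI = 0)
  new("CohortConfig",
      nSubjects = as.integer(nSubjects), nParcels = as.integer(nParcels),
      nModules = as.integer(nModules), featureNames = feats,
      moduleProfiles = moduleProfiles,
      ageRangeWeeks = c(37.43, 44.71),
      ageSlopes = as.numeric(ageSlopes),
      ageGradientAxis = c(0, 1, 0),
      sexEffects = as.numeric(sexEffects),
      noiseSd = noiseSd, seed = as.integer(seed))
}

#' Mutually orthogonal module mean profiles
#'
#' Random K x F matrix with mutually orthogonal rows (QR of a Gaussian
#' matrix), scaled to a common row norm. Orthogonality makes
#' between-module profile correlations near zero, so modules are
#' identifiable in the similarity network. With \code{scale = sqrt(F)}
#' each feature's between-module spread is about 1, matching the unit
#' inter-regional standard deviation that cortex-wide z-scoring imposes
#' on real features.
#'
#' @param K modules, \code{K <= F}.
#' @param nFeatures feature-space dimension.
#' @param seed RNG seed.
#' @param scale row norm of each profile.
#' @return K x F numeric matrix with orthogonal rows of norm
#'   \code{scale}.
#' @export
orthogonalProfiles <- function(K, nFeatures, seed = 1L, scale = 1) {
  if (K > nFeatures) stop("need K <= nFeatures for orthogonal profiles")
  withSeed(seed, {
    m <- matrix(stats::rnorm(nFeatures * nFeatures), nFeatures)
    q <- qr.Q(qr(m))
    scale * t(q[, seq_len(K), drop = FALSE])
  })
}

#' Simulate a synthetic cohort on a parcellation
#'
#' Feature value for subject s, parcel p, feature f:
#' \deqn{y = B[m(p), f] + \gamma_f (age_s - \bar{age}) g(p)
#'        + \delta_f 1\{sex_s = M\} + \epsilon}
#' with \eqn{g(p) = (1 + \langle c_p, axis\rangle)/2} a linear
#' posterior-anterior ramp and \eqn{\epsilon \sim N(0, \sigma^2)} iid.
#' Ages are uniform over the configured range; sexes alternate so the
#' cohort is balanced. Fully reproducible from the config seed.
#'
#' @param config a \linkS4class{CohortConfig}.
#' @param scheme the \linkS4class{ParcelScheme} the cohort lives on.
#' @param truthPartition planted module labels (defaults to mirror-symmetric
#'   \code{plantModules} from the config seed).
#' @return list with elements \code{features} (\linkS4class{FeatureTable}),
#'   \code{meta} (data.frame subject_id, age_weeks, sex) and \code{truth}
#'   (\linkS4class{GroundTruth}).
#' @export
simulateCohort <- function(config, scheme = NULL, truthPartition = NULL) {
  validObject(config)
  if (is.null(scheme))
    scheme <- makeParcellation(config@nParcels, seed = config@seed)
  if (nParcels(scheme) != config@nParcels)
    stop("scheme parcel count does not match config")
  if (is.null(truthPartition))
    truthPartition <- plantModules(scheme, config@nModules,
                                   seed = config@seed, mirrorSymmetric = TRUE)
  if (nParcels(truthPartition) != config@nParcels)
    stop("truth partition does not match scheme")
  K <- config@nModules
  if (length(unique(truthPartition@labels)) != K)
    stop("truth partition must use exactly K labels")
  B <- config@moduleProfiles
  if (ncol(B) != length(config@featureNames))
    stop("module profile width does not match feature names")

  S <- config@nSubjects; P <- config@nParcels
  f <- length(config@featureNames)
  withSeed(stageSeed(config@seed, "cohort"), {
    ages <- stats::runif(S, config@ageRangeWeeks[1], config@ageRangeWeeks[2])
    sexes <- rep(c("M", "F"), length.out = S)
    axis <- config@ageGradientAxis
    axis <- axis / sqrt(sum(axis^2))
    g <- as.numeric((1 + centroids(scheme) %*% axis) / 2)
    m <- truthPartition@labels
    base <- B[m, , drop = FALSE]                       # P x F
    ageC <- ages - mean(ages)
    vals <- array(0, dim = c(S, P, f),
                  dimnames = list(sprintf("sub-%03d", seq_len(S)),
                                  seq_len(P), config@featureNames))
    for (s in seq_len(S)) {
      eff <- base +
        outer(g * ageC[s], config@ageSlopes) +
        (sexes[s] == "M") * matrix(config@sexEffects, P, f, byrow = TRUE)
      vals[s, , ] <- eff + matrix(stats::rnorm(P * f, sd = config@noiseSd),
                                  P, f)
    }
    meta <- data.frame(subject_id = dimnames(vals)[[1]],
                       age_weeks = ages, sex = sexes,
                       stringsAsFactors = FALSE)
    list(features = new("FeatureTable", values = vals, zscored = FALSE),
         meta = meta,
         truth = new("GroundTruth", modulePartition = truthPartition,
                     config = config))
  })
}

#' Synthetic reference class labelling with controlled overlap
#'
#' Stands in for a gross cytoarchitectonic reference atlas (e.g. seven
#' tissue classes). With \code{overlap = 1} and \code{C} equal to the truth
#' cluster count it is a relabelled copy of the truth; with
#' \code{overlap = 0} an independent spatially contiguous C-class
#' labelling; in between, a \code{(1 - overlap)} fraction of parcels is
#' reassigned from the (relabelled) truth to the independent labelling.
#'
#' @param scheme a \linkS4class{ParcelScheme}.
#' @param truthPartition the planted module labels.
#' @param C number of reference classes.
#' The reassigned set is a spatially contiguous cap (nearest parcels to a
#' random anchor), not a scatter of isolated parcels, so the blend stays
#' spatially coherent and its distance to the truth grows smoothly with
#' \code{1 - overlap}.
#'
#' @param overlap real in [0, 1].
#' @param seed RNG seed.
#' @return a \linkS4class{Partition} with labels \code{1..C} (labels absent
#'   after mixing are possible only at extreme overlap values).
#' @export
makeReferenceClasses <- function(scheme, truthPartition, C = 7L,
                                 overlap = 0.5, seed = 1L) {
  if (C < 1) stop("C must be >= 1")
  if (overlap < 0 || overlap > 1) stop("overlap must lie in [0, 1]")
  n <- nParcels(scheme)
  indep <- plantModules(scheme, C, seed = stageSeed(seed, "reference"),
                        mirrorSymmetric = FALSE)
  K <- nClusters(truthPartition)
  withSeed(stageSeed(seed, "reference-mix"), {
    if (overlap == 0) return(indep)
    # relabelled copy of the truth (labels shuffled onto 1..K)
    relab <- sample.int(K)
    base <- relab[match(truthPartition@labels,
                        sort(unique(truthPartition@labels)))]
    if (C > K) base <- base  # extra class labels only enter via the mix
    labels <- base
    nFlip <- round((1 - overlap) * n)
    if (nFlip > 0) {
      anchor <- sample.int(n, 1)
      d <- as.numeric(centroids(scheme) %*% centroids(scheme)[anchor, ])
      flip <- order(d, decreasing = TRUE)[seq_len(nFlip)]
      labels[flip] <- indep@labels[flip]
    }
    newPartition(labels)
  })
}
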
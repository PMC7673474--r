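#' @include AllClasses.R
NULL

.runConfigDefaults <- function() list(
  cohort_dir = NULL,
  results_dir = NULL,
  n_subjects = 241L,
  n_parcels = 150L,
  n_modules = 7L,
  noise_sd = 0.5,
  k_target = 7L,
  free_k = TRUE,
  damping = 0.9,
  max_iter = 1000L,
  conv_iter = 100L,
  n_perm = 500L,
  bootstrap_draw_size = 20L,
  bootstrap_iterations = 500L,
  reference_classes = 7L,
  reference_overlap = 0.5,
  correction_q = 0.05,
  pfdr_lambda = 0.5,
  seed = 1L
)

#' Build or load a pipeline run configuration
#'
#' Unknown keys are an error (fail-fast), so typos in a config file never
#' silently fall back to defaults. Every stochastic stage derives its own
#' seed deterministically from \code{seed} plus a stage tag.
#'
#' @param ... overrides of the default fields (see
#'   \code{\link{runPipeline}}).
#' @param file optional JSON config file; \code{...} overrides win.
#' @return a validated named list of class \code{msnRunConfig}.
#' @export
runConfig <- function(..., file = NULL) {
  cfg <- .runConfigDefaults()
  ov <- list()
  if (!is.null(file))
    ov <- jsonlite::read_json(file, simplifyVector = TRUE)
  ov <- utils::modifyList(ov, list(...))
  unknown <- setdiff(names(ov), names(cfg))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(cfg, ov)
  for (k in c("n_subjects", "n_parcels", "n_modules", "k_target",
              "max_iter", "conv_iter", "n_perm", "bootstrap_draw_size",
              "bootstrap_iterations", "reference_classes", "seed"))
    cfg[[k]] <- as.integer(cfg[[k]])
  structure(cfg, class = "msnRunConfig")
}

.apConfigOf <- function(cfg) {
  apConfig(damping = cfg$damping, maxIter = cfg$max_iter,
           convIter = cfg$conv_iter, seed = stageSeed(cfg$seed, "ap"))
}

#' Simulate a cohort to disk
#'
#' Generates the parcellation, planted modules and synthetic cohort from
#' the run configuration and writes \code{scheme.tsv},
#' \code{features.tsv}, \code{meta.tsv} and \code{truth.json} to
#' \code{cohort_dir}.
#'
#' @param cfg an \code{msnRunConfig} (see \code{\link{runConfig}}).
#' @return the cohort directory, invisibly.
#' @export
cmdSimulate <- function(cfg) {
  if (is.null(cfg$cohort_dir)) stop("config needs cohort_dir")
  cc <- defaultCohortConfig(nSubjects = cfg$n_subjects,
                            nParcels = cfg$n_parcels,
                            nModules = cfg$n_modules,
                            noiseSd = cfg$noise_sd, seed = cfg$seed)
  scheme <- makeParcellation(cfg$n_parcels, seed = cfg$seed)
  cohort <- simulateCohort(cc, scheme)
  writeCohort(cohort, scheme, cfg$cohort_dir)
  message("cohort written to ", cfg$cohort_dir)
  invisible(cfg$cohort_dir)
}

#' Run the full analysis pipeline
#'
#' End-to-end orchestration over an in-memory or on-disk cohort: group
#' MSN, free-k and fixed-k clustering, leave-one-feature-out and
#' single-feature-SCN agreement rankings, Dice and spin-test comparison
#' against the reference classes, bootstrap coincidence, and the age/sex
#' statistics for edges, nodes, modules and single features. When
#' \code{results_dir} is set, the main artifacts are written as TSV/JSON
#' with a manifest.
#'
#' @param cfg an \code{msnRunConfig}.
#' @param cohort optional list (\code{scheme}, \code{features},
#'   \code{meta}, \code{truthPartition}); when NULL it is read from
#'   \code{cfg$cohort_dir}.
#' @param stages character vector selecting stages:
#'   any of \code{"cluster"}, \code{"agreement"}, \code{"reference"},
#'   \code{"bootstrap"}, \code{"subjects"}, \code{"stats"}. Defaults to
#'   all.
#' @return named list of stage results (invisible components documented
#'   per stage function).
#' @export
runPipeline <- function(cfg, cohort = NULL,
                        stages = c("cluster", "agreement", "reference",
                                   "bootstrap", "subjects", "stats")) {
  if (is.null(cohort)) {
    if (is.null(cfg$cohort_dir)) stop("config needs cohort_dir")
    cohort <- readCohort(cfg$cohort_dir)
  }
  scheme <- cohort$scheme
  raw <- cohort$features
  ages <- cohort$meta$age_weeks
  sexes <- cohort$meta$sex
  apcfg <- .apConfigOf(cfg)
  out <- list(config = cfg)

  ztab <- zscoreFeatures(raw)
  subjMats <- subjectMSNs(ztab)
  gm <- groupMSN(subjMats)
  out$groupMSN <- gm

  if ("cluster" %in% stages) {
    out$freeK <- suppressWarnings(affinityPropagation(gm, apcfg))
    out$fixedK <- clusterFixedK(gm, cfg$k_target, apcfg)
    if (!is.null(cohort$truthPartition))
      out$truthNVI <- normalizedVI(out$fixedK@partition,
                                   cohort$truthPartition)
  }

  if ("agreement" %in% stages) {
    feats <- featureNames(raw)
    ref <- out$fixedK
    loo <- vapply(feats, function(f) {
      m <- leaveOneOutGroupMSN(raw, f)
      normalizedVI(clusterFixedK(m, cfg$k_target, apcfg)@partition,
                   ref@partition)
    }, numeric(1))
    scn <- vapply(feats, function(f) {
      m <- singleFeatureSCN(raw, f)
      normalizedVI(clusterFixedK(m, cfg$k_target, apcfg)@partition,
                   ref@partition)
    }, numeric(1))
    out$looNVI <- sort(loo)
    out$scnNVI <- sort(scn)
  }

  if ("reference" %in% stages) {
    truth <- cohort$truthPartition
    if (!is.null(truth)) {
      refClasses <- makeReferenceClasses(
        scheme, truth, C = cfg$reference_classes,
        overlap = cfg$reference_overlap,
        seed = stageSeed(cfg$seed, "refclasses"))
      part <- out$fixedK@partition
      out$referenceClasses <- refClasses
      out$dice <- diceOverlap(part, refClasses)
      out$spin <- spinTest(scheme, part, refClasses, nPerm = cfg$n_perm,
                           seed = stageSeed(cfg$seed, "spin"))
    }
  }

  if ("bootstrap" %in% stages) {
    out$coincidence <- bootstrapStability(
      subjMats, drawSize = cfg$bootstrap_draw_size,
      iterations = cfg$bootstrap_iterations,
      kTarget = if (cfg$free_k) NULL else cfg$k_target,
      config = apcfg, seed = stageSeed(cfg$seed, "bootstrap"))
  }

  if ("subjects" %in% stages) {
    out$subjectConsistency <- clusterSubjects(
      subjMats, out$fixedK@partition, kTarget = cfg$k_target,
      config = apcfg)
  }

  if ("stats" %in% stages) {
    out$edgeAge <- edgeAgeAnalysis(subjMats, ages, q = cfg$correction_q)
    out$nodeAge <- nodeStrengthAgeAnalysis(subjMats, ages,
                                           q = cfg$correction_q)
    out$sex <- sexAnalysis(subjMats, sexes, q = cfg$correction_q)
    out$moduleAge <- moduleAgeAnalysis(subjMats, out$fixedK@partition,
                                       ages, q = cfg$correction_q)
    out$featureAge <- featureAgeAnalysis(raw, ages, q = cfg$correction_q)
    out$edgeAgeClusters <- clusterEdgeAgeMatrix(out$edgeAge$edgeAgeMatrix,
                                                config = apcfg)
  }

  if (!is.null(cfg$results_dir)) .writeResults(out, cfg)
  invisible(out)
}

.writeResults <- function(out, cfg) {
  dir.create(cfg$results_dir, showWarnings = FALSE, recursive = TRUE)
  rd <- cfg$results_dir
  artifacts <- character()
  put <- function(name, writer) {
    path <- file.path(rd, name)
    writer(path)
    artifacts <<- c(artifacts, name)
  }
  put("group_msn.tsv", function(p) writeSimilarityMatrix(out$groupMSN, p))
  if (!is.null(out$freeK))
    put("partition_free_k.tsv", function(p)
      writePartition(out$freeK@partition, p, exemplars(out$freeK)))
  if (!is.null(out$fixedK))
    put("partition_fixed_k.tsv", function(p)
      writePartition(out$fixedK@partition, p, exemplars(out$fixedK)))
  if (!is.null(out$looNVI))
    put("loo_nvi.tsv", function(p)
      utils::write.table(
        data.frame(feature = names(out$looNVI), nvi = out$looNVI),
        p, sep = "\t", quote = FALSE, row.names = FALSE))
  if (!is.null(out$scnNVI))
    put("scn_nvi.tsv", function(p)
      utils::write.table(
        data.frame(feature = names(out$scnNVI), nvi = out$scnNVI),
        p, sep = "\t", quote = FALSE, row.names = FALSE))
  if (!is.null(out$dice))
    put("dice.tsv", function(p)
      utils::write.table(out$dice, p, sep = "\t", quote = FALSE))
  if (!is.null(out$spin))
    put("spin.json", function(p)
      jsonlite::write_json(list(
        observed_nvi = out$spin@observed, p_value = out$spin@pValue,
        n_perm = out$spin@nPerm, seed = out$spin@seed),
        p, digits = NA, auto_unbox = TRUE))
  if (!is.null(out$coincidence))
    put("coincidence.tsv", function(p)
      utils::write.table(simValues(out$coincidence), p, sep = "\t",
                         quote = FALSE))
  for (nm in c("edgeAge", "nodeAge", "moduleAge", "featureAge")) {
    if (is.null(out[[nm]])) next
    tab <- if (is.data.frame(out[[nm]])) out[[nm]] else
      out[[nm]][[intersect(c("edges", "nodes"), names(out[[nm]]))[1]]]
    local({
      nm2 <- paste0("stats_", nm, ".tsv"); tab2 <- tab
      put(nm2, function(p)
        utils::write.table(tab2, p, sep = "\t", quote = FALSE,
                           row.names = FALSE))
    })
  }
  summary <- list(
    seed = cfg$seed,
    free_k = if (!is.null(out$freeK)) out$freeK@k,
    fixed_k = if (!is.null(out$fixedK)) out$fixedK@k,
    fixed_k_preference = if (!is.null(out$fixedK)) out$fixedK@preference,
    truth_nvi = out$truthNVI,
    spin_p = if (!is.null(out$spin)) out$spin@pValue,
    artifacts = artifacts)
  jsonlite::write_json(summary[!vapply(summary, is.null, logical(1))],
                       file.path(rd, "manifest.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(rd)
}
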
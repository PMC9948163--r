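# Pipeline orchestration: run curate -> eda -> scaffolds -> landscape ->
# qsar on one configuration, writing every stage's outputs plus a manifest
# into a run directory.

#' Default pipeline configuration
#'
#' Builds a validated pipeline configuration. Either `input` points to a
#' ChEMBL-style CSV, or `synthetic` holds a [synthConfig()] whose generated
#' table is used (and written alongside the results).
#'
#' @param input Path to a bioactivity CSV (or `NULL` to use `synthetic`).
#' @param synthetic A [synthConfig()] (used when `input` is `NULL`).
#' @param out_dir Run directory root.
#' @param dedup Duplicate policy for curation.
#' @param fingerprints Fingerprint kinds for the landscape stage.
#' @param sim_threshold,act_threshold SAS-map thresholds.
#' @param min_gen_count Minimum cliff count for AC generators.
#' @param qsar_mode `"safe"` or `"published-parity"`.
#' @param qsar_algorithms Bench subset (default: the full 12).
#' @param qsar_fingerprint Fingerprint for the QSAR bench.
#' @param folds CV folds.
#' @param seed Seed used for oversampling/split.
#' @return List of class `pipeline_config`.
#' @export
pipelineConfig <- function(input = NULL, synthetic = synthConfig(),
                           out_dir = "chemlandscape-run",
                           dedup = "first",
                           fingerprints = c("ecfp4", "maccs", "pubchem"),
                           sim_threshold = 0.9, act_threshold = 2.0,
                           min_gen_count = 2,
                           qsar_mode = "safe",
                           qsar_algorithms = names(.benchAlgorithms()),
                           qsar_fingerprint = "pubchem",
                           folds = 10, seed = 42) {
  if (!is.null(input) && !file.exists(input))
    stop("pipelineConfig: input file does not exist: ", input)
  stopifnot(all(fingerprints %in% names(.FP_KINDS)),
            qsar_fingerprint %in% names(.FP_KINDS),
            qsar_mode %in% c("safe", "published-parity"),
            sim_threshold > 0, sim_threshold < 1, act_threshold > 0)
  cfg <- list(input = input, synthetic = synthetic, out_dir = out_dir,
              dedup = dedup, fingerprints = fingerprints,
              sim_threshold = sim_threshold, act_threshold = act_threshold,
              min_gen_count = min_gen_count, qsar_mode = qsar_mode,
              qsar_algorithms = qsar_algorithms,
              qsar_fingerprint = qsar_fingerprint, folds = folds,
              seed = seed)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys mirror the [pipelineConfig()] arguments
#'   (`synthetic` is a nested mapping of [synthConfig()] arguments).
#' @return List of class `pipeline_config`.
#' @export
readPipelineConfig <- function(path) {
  stopifnot(file.exists(path))
  y <- yaml::read_yaml(path)
  if (!is.null(y$synthetic)) y$synthetic <- do.call(synthConfig, y$synthetic)
  do.call(pipelineConfig, y)
}

#' Run the full analysis pipeline
#'
#' Executes curation, exploratory property analysis + PCA, scaffold
#' analysis, activity-landscape mapping and the QSAR bench in order,
#' writing each stage's tables under `out_dir/<stage>/` and a manifest
#' (inputs, parameters, seed, row counts at every filter) at the root.
#' A stage failure aborts with the stage name; completed outputs are kept.
#'
#' @param config A [pipelineConfig()].
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
runPipeline <- function(config = pipelineConfig(), quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  root <- config$out_dir
  dir.create(root, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)
  manifest <- list(parameters = config[setdiff(names(config),
                                               c("synthetic"))],
                   seed = config$seed)
  stage <- function(name, expr) {
    say("[", name, "] running")
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  # -- input -----------------------------------------------------------------
  truth <- NULL
  records <- stage("input", {
    if (!is.null(config$input)) {
      readBioactivityTable(config$input)
    } else {
      ds <- generateDataset(config$synthetic)
      truth <- ds$truth
      writeSyntheticDataset(ds, file.path(root, "synthetic.csv"),
                            file.path(root, "synthetic-truth.json"))
      ds$table
    }
  })
  manifest$input_rows <- nrow(records)

  # -- curate ----------------------------------------------------------------
  curated <- stage("curate", curateBioactivities(records,
                                                 dedup = config$dedup))
  writeCurated(curated, file.path(root, "curated"))
  manifest$curation <- curationLog(curated)

  # -- eda -------------------------------------------------------------------
  eda <- stage("eda", {
    m <- molecules(curated)
    props <- computeProperties(m$smiles, ids = m$molecule_id)
    gs <- summarizeGroups(curated, properties = props)
    pca <- runPropertyPCA(props)
    dir.create(file.path(root, "eda"), showWarnings = FALSE)
    utils::write.csv(gs$stats, file.path(root, "eda", "group-stats.csv"),
                     row.names = FALSE)
    utils::write.csv(data.frame(property = names(gs$u_pvalue),
                                u_pvalue = gs$u_pvalue),
                     file.path(root, "eda", "mann-whitney.csv"),
                     row.names = FALSE)
    ld <- rbind(as.data.frame(pca$loadings),
                `cumulated variance (%)` = pca$cumulative_variance)
    utils::write.csv(ld, file.path(root, "eda", "pca-loadings.csv"))
    utils::write.csv(as.data.frame(pca$scores),
                     file.path(root, "eda", "pca-scores.csv"))
    list(properties = props, groups = gs, pca = pca)
  })
  manifest$eda <- list(n_properties = ncol(eda$properties),
                       cumulative_variance =
                         unname(eda$pca$cumulative_variance))

  # -- scaffolds -------------------------------------------------------------
  scaffold_set <- stage("scaffolds", buildScaffoldTable(curated))
  diversity <- stage("scaffolds", diversityMetrics(curated))
  dir.create(file.path(root, "scaffolds"), showWarnings = FALSE)
  utils::write.csv(scaffolds(scaffold_set),
                   file.path(root, "scaffolds", "scaffolds.csv"),
                   row.names = FALSE)
  utils::write.csv(diversity,
                   file.path(root, "scaffolds", "diversity.csv"),
                   row.names = FALSE)
  manifest$scaffolds <- list(
    n_scaffolds = nrow(scaffolds(scaffold_set)),
    n_csk = length(unique(scaffolds(scaffold_set)$csk_smiles[
      !scaffolds(scaffold_set)$acyclic])))

  # -- landscape -------------------------------------------------------------
  landscape <- stage("landscape", {
    dir.create(file.path(root, "landscape"), showWarnings = FALSE)
    maps <- list()
    for (kind in config$fingerprints) {
      sm <- sasMap(curated, kind, config$sim_threshold,
                   config$act_threshold)
      utils::write.csv(landscapePairs(sm),
                       file.path(root, "landscape",
                                 paste0("pairs-", kind, ".csv")),
                       row.names = FALSE)
      maps[[kind]] <- sm
    }
    acs <- lapply(maps, activityCliffs)
    cons <- if (length(maps) >= 2) consensusACs(maps) else acs[[1]]
    gens <- acGenerators(acs[[config$fingerprints[1]]],
                         min_count = config$min_gen_count)
    utils::write.csv(cons, file.path(root, "landscape", "consensus-acs.csv"),
                     row.names = FALSE)
    utils::write.csv(gens, file.path(root, "landscape", "generators.csv"),
                     row.names = FALSE)
    list(maps = maps, acs = acs, consensus = cons, generators = gens)
  })
  manifest$landscape <- list(
    n_pairs = nrow(landscapePairs(landscape$maps[[1]])),
    n_acs = vapply(landscape$acs, nrow, integer(1)),
    n_consensus = nrow(landscape$consensus))

  # -- qsar ------------------------------------------------------------------
  bench <- stage("qsar", qsarBench(
    curated, kind = config$qsar_fingerprint, mode = config$qsar_mode,
    algorithms = config$qsar_algorithms, folds = config$folds,
    seed = config$seed))
  dir.create(file.path(root, "qsar"), showWarnings = FALSE)
  utils::write.csv(bench, file.path(root, "qsar", "bench.csv"),
                   row.names = FALSE)
  manifest$qsar <- list(majority_baseline = attr(bench,
                                                 "majority_baseline"),
                        n_features = attr(bench, "n_features"),
                        best_test_accuracy =
                          max(bench$accuracy_test, na.rm = TRUE))

  jsonlite::write_json(manifest, file.path(root, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("pipeline complete: ", root)
  invisible(list(curated = curated, eda = eda,
                 scaffolds = scaffold_set, diversity = diversity,
                 landscape = landscape, bench = bench, truth = truth,
                 manifest = manifest))
}
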
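#' Run one pipeline stage
#'
#' Command-line-style entry point binding the pipeline stages together. Each
#' stage reads/writes plain-text artifacts in a run directory and drops a
#' \code{manifest.json} (command, parameters, seed, package version, counts)
#' beside its outputs, so every run is reproducible from its manifest.
#'
#' Commands and their config entries:
#' \describe{
#'   \item{simulate}{generate a synthetic benchmark; config: any
#'     [fixtureConfig()] field; writes \code{ontology.obo} and the dataset.}
#'   \item{build-dataset}{config: \code{ontology} (OBO path), \code{root},
#'     \code{minMembers}, optional \code{versionTag}; writes the unsplit
#'     dataset.}
#'   \item{split}{config: \code{dataset} (dir), \code{train},
#'     \code{validation}, \code{test}, \code{seed}.}
#'   \item{train}{config: \code{dataset} (dir), optional \code{weighted}
#'     (default TRUE), \code{beta}, and any [encoderConfig()] field; writes
#'     a model directory.}
#'   \item{predict}{config: \code{model} (dir), \code{smiles} (text file,
#'     one SMILES per line), optional \code{threshold}; writes
#'     \code{predictions.json}/\code{.tsv}; untokenizable inputs become
#'     per-item error records, never a failure.}
#'   \item{evaluate}{config: \code{model}, \code{dataset} (split dir),
#'     optional \code{partition} (default "test"); writes a metrics report.}
#'   \item{compare-specificity}{config: \code{modelA}, \code{modelB},
#'     \code{dataset}, \code{ontology}; writes the four-way table.}
#'   \item{paths}{config: \code{ontology}, \code{sources} (comma-separated
#'     CURIEs), \code{target}; writes the path-length histogram TSV.}
#' }
#'
#' @param command one of the stage names above
#' @param config named list of stage parameters (e.g. parsed from a YAML
#'   file with \code{yaml::read_yaml}, command-line overrides merged in)
#' @param outDir run directory for outputs
#' @return the stage's main result, invisibly
#' @export
runStage <- function(command, config = list(), outDir = ".") {
  command <- match.arg(command, c("simulate", "build-dataset", "split",
                                  "train", "predict", "evaluate",
                                  "compare-specificity", "paths"))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  result <- switch(command,
    "simulate" = .stageSimulate(config, outDir),
    "build-dataset" = .stageBuildDataset(config, outDir),
    "split" = .stageSplit(config, outDir),
    "train" = .stageTrain(config, outDir),
    "predict" = .stagePredict(config, outDir),
    "evaluate" = .stageEvaluate(config, outDir),
    "compare-specificity" = .stageCompare(config, outDir),
    "paths" = .stagePaths(config, outDir))
  manifest <- list(command = command, config = config,
                   package = as.character(utils::packageVersion("OntoSmiles")),
                   counts = attr(result, "stageCounts"),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, na = "null", force = TRUE)
  invisible(result)
}

.cfg <- function(config, name, default = NULL, required = is.null(default)) {
  if (!is.null(config[[name]])) return(config[[name]])
  if (required) stop("config entry '", name, "' is required")
  default
}

.fixtureFromConfig <- function(config) {
  known <- names(formals(fixtureConfig))
  do.call(fixtureConfig, config[intersect(names(config), known)])
}

.encoderFromConfig <- function(config) {
  known <- names(formals(encoderConfig))
  do.call(encoderConfig, config[intersect(names(config), known)])
}

.stageSimulate <- function(config, outDir) {
  fc <- .fixtureFromConfig(config)
  bench <- generateBenchmark(fc)
  writeOBO(bench$graph, file.path(outDir, "ontology.obo"))
  writeLabeledDataset(bench$dataset, file.path(outDir, "dataset"))
  res <- bench$dataset
  attr(res, "stageCounts") <- list(classes = length(bench$graph),
                              molecules = ncol(bench$dataset),
                              labels = nrow(bench$dataset))
  res
}

.stageBuildDataset <- function(config, outDir) {
  graph <- loadOBO(.cfg(config, "ontology"))
  sel <- selectLabelClasses(graph, .cfg(config, "root"),
                            .cfg(config, "minMembers"),
                            versionTag = .cfg(config, "versionTag", ""))
  ds <- buildLabeledDataset(graph, sel)
  writeLabeledDataset(ds, file.path(outDir, "dataset"))
  attr(ds, "stageCounts") <- list(molecules = ncol(ds), labels = nrow(ds))
  ds
}

.stageSplit <- function(config, outDir) {
  ds <- readLabeledDataset(.cfg(config, "dataset"))
  sc <- splitConfig(train = .cfg(config, "train", 0.85),
                    validation = .cfg(config, "validation", 0.0225),
                    test = .cfg(config, "test", 0.1275),
                    seed = .cfg(config, "seed", 0L))
  ds <- splitDataset(ds, sc)
  writeLabeledDataset(ds, file.path(outDir, "dataset"))
  attr(ds, "stageCounts") <- as.list(table(splitAssignments(ds)))
  ds
}

.stageTrain <- function(config, outDir) {
  ds <- readLabeledDataset(.cfg(config, "dataset"))
  ec <- .encoderFromConfig(config)
  train <- datasetPartition(ds, "train")
  validation <- datasetPartition(ds, "validation")
  vocab <- buildVocabulary(lapply(molecules(train)$smiles, tokenizeSmiles))
  weights <- NULL
  if (isTRUE(.cfg(config, "weighted", TRUE))) {
    mc <- S4Vectors::metadata(ds)$memberCounts
    weights <- classWeights(mc, beta = .cfg(config, "beta", 0.99))
    writeClassWeights(weights, file.path(outDir, "class_weights.tsv"))
  }
  model <- trainClassifier(train, validation, vocab, weights, ec)
  saveModel(model, file.path(outDir, "model"))
  attr(model, "stageCounts") <- list(train = ncol(train),
                                validation = ncol(validation),
                                bestEpoch = model@bestEpoch)
  model
}

.stagePredict <- function(config, outDir) {
  model <- loadModel(.cfg(config, "model"))
  smiles <- readLines(.cfg(config, "smiles"))
  smiles <- smiles[nzchar(smiles)]
  preds <- predict(model, smiles, threshold = .cfg(config, "threshold", 0.5))
  writePredictions(preds, file.path(outDir, "predictions.json"),
                   file.path(outDir, "predictions.tsv"))
  attr(preds, "stageCounts") <- list(inputs = length(smiles),
                                failed = nrow(itemErrors(preds)))
  preds
}

.stageEvaluate <- function(config, outDir) {
  model <- loadModel(.cfg(config, "model"))
  ds <- readLabeledDataset(.cfg(config, "dataset"))
  part <- datasetPartition(ds, .cfg(config, "partition", "test"))
  preds <- predict(model, molecules(part)$smiles,
                   threshold = .cfg(config, "threshold", 0.5))
  report <- f1Report(preds, part)
  writeMetricsReport(report, file.path(outDir, "metrics.json"),
                     file.path(outDir, "per_class_f1.tsv"))
  attr(report, "stageCounts") <- list(molecules = report@nMolecules,
                                 labels = report@nLabels)
  report
}

.stageCompare <- function(config, outDir) {
  graph <- loadOBO(.cfg(config, "ontology"))
  ds <- readLabeledDataset(.cfg(config, "dataset"))
  part <- datasetPartition(ds, .cfg(config, "partition", "test"))
  thr <- .cfg(config, "threshold", 0.5)
  modelA <- loadModel(.cfg(config, "modelA"))
  modelB <- loadModel(.cfg(config, "modelB"))
  predsA <- predict(modelA, molecules(part)$smiles, threshold = thr)
  predsB <- predict(modelB, molecules(part)$smiles, threshold = thr)
  tab <- specificityComparison(predsA, predsB, part, graph)
  jsonlite::write_json(
    list(counts = as.list(specificityCounts(tab)),
         percentages = as.list(specificityPercentages(tab)),
         nPairs = tab@nPairs),
    file.path(outDir, "specificity.json"), auto_unbox = TRUE, digits = NA)
  attr(tab, "stageCounts") <- list(pairs = tab@nPairs)
  tab
}

.stagePaths <- function(config, outDir) {
  graph <- loadOBO(.cfg(config, "ontology"))
  sources <- trimws(strsplit(.cfg(config, "sources"), ",")[[1]])
  hist <- countPaths(graph, sources, .cfg(config, "target"))
  writePathHistogram(hist, file.path(outDir, "path_histogram.tsv"))
  attr(hist, "stageCounts") <- list(paths = sum(pathCounts(hist)))
  hist
}

#' Persist class weights as a TSV
#'
#' Columns: label CURIE, member count |C|, weight.
#'
#' @param weights a [ClassWeights-class]
#' @param path output TSV path
#' @return \code{path}, invisibly
#' @export
writeClassWeights <- function(weights, path) {
  tb <- data.frame(label = names(weights@weights),
                   members = weights@memberCounts[names(weights@weights)],
                   weight = weights@weights)
  utils::write.table(tb, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
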
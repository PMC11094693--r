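#' Train the Transformer multi-label classifier
#'
#' Trains a from-scratch Transformer encoder with a sigmoid multi-label head
#' on the tokenized SMILES of the training partition, minimizing the
#' (optionally class-balanced) multi-label binary cross-entropy by Adam.
#' After each epoch the datapoint-averaged micro F1 on the validation
#' partition is logged and the best-validation parameters are kept; the
#' returned model carries that checkpoint. Fully seeded: the same
#' configuration, data and seed reproduce the same loss trajectory.
#'
#' @param train,validation [LabeledDataset-class] partitions sharing one
#'   label order (see [datasetPartition()])
#' @param vocab a [TokenVocabulary-class] covering the training tokens
#' @param weights a [ClassWeights-class] aligned with the label order, or
#'   NULL for unweighted training
#' @param config an [encoderConfig()]
#' @return a [TrainedModel-class]
#' @export
trainClassifier <- function(train, validation, vocab, weights = NULL,
                            config = encoderConfig()) {
  if (ncol(train) == 0L) stop("empty training partition")
  if (!identical(labelOrder(train), labelOrder(validation)))
    stop("train and validation partitions must share the label order")
  labels <- labelOrder(train)
  w <- rep(1, length(labels))
  if (!is.null(weights)) {
    wv <- if (is(weights, "ClassWeights")) weights@weights else weights
    if (!all(labels %in% names(wv))) stop("weights do not cover the label order")
    w <- unname(wv[labels])
  }
  enc <- function(ds) {
    sm <- molecules(ds)$smiles
    idx <- matrix(0L, nrow = length(sm), ncol = config$maxLength)
    lens <- integer(length(sm))
    for (i in seq_along(sm)) {
      tk <- tokenizeSmiles(sm[i])
      v <- encodeTokens(vocab, tk, config$maxLength, truncate = config$truncate)
      idx[i, ] <- v
      lens[i] <- min(length(tk@tokens), config$maxLength - 1L) + 1L
    }
    list(idx = idx, lens = lens, y = unname(labelMatrix(ds)))
  }
  trn <- enc(train)
  val <- if (ncol(validation) > 0L) enc(validation) else NULL
  nTrain <- nrow(trn$idx)
  C <- length(labels)
  log <- data.frame(epoch = integer(), trainLoss = numeric(),
                    valMicroF1 = numeric())
  result <- .withSeed(config$seed, {
    params <- .initParams(config, vocabularySize(vocab), C)
    state <- .adamInit(params)
    best <- list(params = params, f1 = -Inf, epoch = 0L)
    sinceBest <- 0L
    for (epoch in seq_len(config$epochs)) {
      perm <- sample.int(nTrain)
      starts <- seq(1L, nTrain, by = config$batchSize)
      epochLoss <- 0
      for (s in starts) {
        take <- perm[s:min(s + config$batchSize - 1L, nTrain)]
        B <- length(take)
        Xflat <- as.integer(t(trn$idx[take, , drop = FALSE]))
        fw <- .forwardBatch(params, config, Xflat, trn$lens[take], training = TRUE)
        probs <- .sigmoid(fw$logits)
        tgt <- trn$y[take, , drop = FALSE]
        loss <- weightedMultilabelLoss(probs, tgt, setNames(w, labels))
        if (!is.finite(loss)) stop("training diverged: non-finite loss at epoch ", epoch)
        dZ <- (probs - tgt) * rep(w, each = B) / (B * C)
        grads <- .backwardBatch(params, config, fw$cache, dZ)
        upd <- .adamStep(params, grads, state, config$learningRate)
        params <- upd$params; state <- upd$state
        epochLoss <- epochLoss + loss * B
      }
      epochLoss <- epochLoss / nTrain
      valF1 <- NA_real_
      if (!is.null(val)) {
        vp <- .inferProbs(params, config, val$idx, val$lens)
        valF1 <- mean(vapply(seq_len(nrow(vp)), function(i)
          .setF1(vp[i, ] >= 0.5, val$y[i, ] == 1), numeric(1)))
      }
      log[nrow(log) + 1L, ] <- list(epoch, epochLoss, valF1)
      track <- if (is.na(valF1)) -epochLoss else valF1
      if (track > best$f1) {
        best <- list(params = params, f1 = track, epoch = epoch)
        sinceBest <- 0L
      } else {
        sinceBest <- sinceBest + 1L
        if (sinceBest >= config$patience) break
      }
    }
    best
  })
  new("TrainedModel", params = result$params, config = config, vocab = vocab,
      labelOrder = labels, trainingLog = log,
      bestEpoch = as.integer(result$epoch),
      vocabHash = .hashCharacter(vocab@tokens))
}

# batched inference over a pre-encoded index matrix; deterministic (no
# dropout) and independent of the batching used
.inferProbs <- function(params, config, idx, lens, batchSize = 64L) {
  n <- nrow(idx)
  out <- matrix(NA_real_, n, ncol(params$Wh))
  for (s in seq(1L, n, by = batchSize)) {
    take <- s:min(s + batchSize - 1L, n)
    Xflat <- as.integer(t(idx[take, , drop = FALSE]))
    fw <- .forwardBatch(params, config, Xflat, lens[take],
                        training = FALSE, keepCache = FALSE)
    out[take, ] <- .sigmoid(fw$logits)
  }
  out
}

setMethod("show", "TrainedModel", function(object) {
  cat("TrainedModel:", object@config$layers, "layers x", object@config$heads,
      "heads, d =", object@config$embeddingDim, "\n  labels:",
      length(object@labelOrder), " vocab:", vocabularySize(object@vocab),
      " best epoch:", object@bestEpoch, "\n")
})

#' @rdname TrainedModel-class
#' @param x a TrainedModel
#' @export
trainingLog <- function(x) x@trainingLog

#' Predict label classes for SMILES strings
#'
#' Tokenizes and encodes each input, runs the encoder in evaluation mode
#' (deterministic, batch-size independent) and applies the decision
#' threshold: the predicted set is every label with probability >= the
#' threshold. Inputs that fail tokenization or exceed the length limit are
#' reported per item in the result's \code{itemErrors}; they never abort the
#' batch.
#'
#' @param object a [TrainedModel-class]
#' @param smiles character vector of SMILES strings
#' @param threshold decision threshold in (0, 1); 0.5 by default
#' @param batchSize inference batch size
#' @return a [PredictionSet-class]
#' @export
setMethod("predict", "TrainedModel",
function(object, smiles, threshold = 0.5, batchSize = 64L) {
  stopifnot(threshold > 0, threshold < 1)
  smiles <- as.character(smiles)
  config <- object@config
  n <- length(smiles)
  idx <- matrix(0L, n, config$maxLength)
  lens <- integer(n)
  errs <- data.frame(index = integer(), smiles = character(),
                     message = character(), stringsAsFactors = FALSE)
  ok <- logical(n)
  for (i in seq_len(n)) {
    res <- tryCatch({
      tk <- tokenizeSmiles(smiles[i])
      v <- encodeTokens(object@vocab, tk, config$maxLength,
                        truncate = config$truncate)
      idx[i, ] <- v
      lens[i] <- min(length(tk@tokens), config$maxLength - 1L) + 1L
      TRUE
    }, error = function(e) conditionMessage(e))
    if (isTRUE(res)) ok[i] <- TRUE
    else errs[nrow(errs) + 1L, ] <- list(i, smiles[i], res)
  }
  probs <- matrix(NA_real_, n, length(object@labelOrder),
                  dimnames = list(NULL, object@labelOrder))
  if (any(ok))
    probs[ok, ] <- .inferProbs(object@params, config,
                               idx[ok, , drop = FALSE], lens[ok], batchSize)
  predicted <- lapply(seq_len(n), function(i) {
    if (!ok[i]) return(character())
    object@labelOrder[probs[i, ] >= threshold]
  })
  new("PredictionSet", smiles = smiles, probabilities = probs,
      threshold = threshold, predicted = predicted, itemErrors = errs)
})

#' @rdname PredictionSet-class
#' @param x a PredictionSet
#' @export
predictedSets <- function(x) x@predicted

#' @rdname PredictionSet-class
#' @export
predictionProbabilities <- function(x) x@probabilities

#' @rdname PredictionSet-class
#' @export
itemErrors <- function(x) x@itemErrors

setMethod("show", "PredictionSet", function(object) {
  cat("PredictionSet:", length(object@smiles), "molecules x",
      ncol(object@probabilities), "labels (threshold", object@threshold, ")\n")
  if (nrow(object@itemErrors))
    cat("  failed inputs:", nrow(object@itemErrors), "\n")
})

#' Attention maps for one SMILES input
#'
#' Runs the encoder in evaluation mode and returns the attention
#' distributions of every layer and head: an array of shape
#' \code{(layers, heads, T, T)} with \code{T} the unpadded sequence length
#' including the CLS position. Row t is the attention distribution of query
#' position t over key positions (padding masked out), so every row sums
#' to 1.
#'
#' @param model a [TrainedModel-class]
#' @param smiles a single SMILES string
#' @return numeric array \code{(layers, heads, T, T)} with token dimnames
#' @export
setMethod("attentionMaps", "TrainedModel", function(model, smiles) {
  config <- model@config
  tk <- tokenizeSmiles(smiles)
  v <- encodeTokens(model@vocab, tk, config$maxLength, truncate = config$truncate)
  len <- min(length(tk@tokens), config$maxLength - 1L) + 1L
  fw <- .forwardBatch(model@params, config, as.integer(v), len,
                      training = FALSE, keepCache = FALSE, storeAttention = TRUE)
  lab <- c(model@vocab@specials[["start"]],
           tk@tokens[seq_len(len - 1L)])
  out <- array(NA_real_, dim = c(config$layers, config$heads, len, len),
               dimnames = list(NULL, NULL, lab, lab))
  for (l in seq_len(config$layers)) for (h in seq_len(config$heads)) {
    A <- fw$attention[[l]][[1L]][[h]]
    out[l, h, , ] <- A[seq_len(len), seq_len(len)]
  }
  out
})

#' Persist / load a trained model as a directory
#'
#' The directory holds the parameter blob (RDS), the configuration and
#' training log (JSON), the vocabulary TSV and the label order.
#'
#' @param model a [TrainedModel-class]
#' @param dir model directory
#' @return \code{dir} (writer) or a [TrainedModel-class] (reader)
#' @export
saveModel <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  saveRDS(model@params, file.path(dir, "params.rds"))
  jsonlite::write_json(
    list(config = model@config, bestEpoch = model@bestEpoch,
         vocabHash = model@vocabHash, trainingLog = model@trainingLog),
    file.path(dir, "model.json"), auto_unbox = TRUE, na = "null", digits = NA)
  writeVocabulary(model@vocab, file.path(dir, "vocabulary.tsv"))
  writeLines(model@labelOrder, file.path(dir, "label_order.txt"))
  invisible(dir)
}

#' @rdname saveModel
#' @export
loadModel <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "model.json"), simplifyVector = TRUE)
  cfg <- meta$config
  cfg$patience <- if (is.null(cfg$patience)) Inf else cfg$patience
  params <- readRDS(file.path(dir, "params.rds"))
  new("TrainedModel", params = params, config = cfg,
      vocab = readVocabulary(file.path(dir, "vocabulary.tsv")),
      labelOrder = readLines(file.path(dir, "label_order.txt")),
      trainingLog = as.data.frame(meta$trainingLog),
      bestEpoch = as.integer(meta$bestEpoch),
      vocabHash = meta$vocabHash)
}

#' Emit predictions as JSON and TSV
#'
#' @param predictions a [PredictionSet-class]
#' @param jsonPath,tsvPath output paths (either may be NULL)
#' @return invisibly, the list written to JSON
#' @export
writePredictions <- function(predictions, jsonPath = NULL, tsvPath = NULL) {
  labs <- colnames(predictions@probabilities)
  items <- lapply(seq_along(predictions@smiles), function(i) {
    list(smiles = predictions@smiles[i],
         probabilities = as.list(setNames(predictions@probabilities[i, ], labs)),
         predicted = predictions@predicted[[i]])
  })
  out <- list(threshold = predictions@threshold, items = items,
              errors = predictions@itemErrors)
  if (!is.null(jsonPath))
    jsonlite::write_json(out, jsonPath, auto_unbox = TRUE, na = "null", digits = NA)
  if (!is.null(tsvPath)) {
    flat <- data.frame(
      smiles = rep(predictions@smiles, each = length(labs)),
      label = rep(labs, length(predictions@smiles)),
      probability = as.vector(t(predictions@probabilities)),
      predicted = as.vector(t(predictions@probabilities >= predictions@threshold)))
    utils::write.table(flat, tsvPath, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(out)
}
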
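# Bag-of-tokens logistic baseline: one binomial regression per label on
# token-count features. On the synthetic motif benchmark the labels are
# decodable from token content by construction, so this baseline certifies
# that the task is learnable independently of the Transformer.

#' Train a bag-of-tokens logistic baseline
#'
#' Builds a molecules x tokens count matrix from the tokenized SMILES and
#' fits one binomial regression per label (via \code{stats::glm.fit}).
#' Perfect separation — expected when a label is exactly decodable from a
#' token — is unproblematic here: the fitted probabilities saturate and the
#' thresholded predictions are what the baseline is used for. Labels that
#' are constant in the training partition fall back to an intercept-only
#' model; aliased feature columns get zero coefficients.
#'
#' @param train a [LabeledDataset-class] partition
#' @param vocab a [TokenVocabulary-class]
#' @return an object of class \code{"tokenBaseline"}
#' @seealso [predictBaseline()]
#' @export
trainTokenBaseline <- function(train, vocab) {
  feats <- setdiff(vocab@tokens, vocab@specials)
  X <- .tokenCountMatrix(molecules(train)$smiles, feats)
  Y <- labelMatrix(train)
  coefs <- matrix(0, ncol(X) + 1L, ncol(Y),
                  dimnames = list(c("(Intercept)", feats), colnames(Y)))
  for (j in seq_len(ncol(Y))) {
    y <- Y[, j]
    if (length(unique(y)) < 2L) {
      prob <- max(min(mean(y), 1 - 1e-6), 1e-6)
      coefs[1L, j] <- log(prob / (1 - prob))
    } else {
      fit <- suppressWarnings(
        stats::glm.fit(cbind(1, X), y, family = stats::binomial()))
      beta <- fit$coefficients
      beta[is.na(beta)] <- 0
      coefs[, j] <- beta
    }
  }
  structure(list(coefficients = coefs, features = feats,
                 labelOrder = colnames(Y)),
            class = "tokenBaseline")
}

.tokenCountMatrix <- function(smiles, features) {
  X <- matrix(0, length(smiles), length(features),
              dimnames = list(NULL, features))
  for (i in seq_along(smiles)) {
    tb <- table(tokenizeSmiles(smiles[i])@tokens)
    hit <- intersect(names(tb), features)
    X[i, hit] <- as.numeric(tb[hit])
  }
  X
}

#' Predict with the bag-of-tokens baseline
#'
#' @param baseline a \code{"tokenBaseline"} from [trainTokenBaseline()]
#' @param smiles character vector of SMILES strings
#' @param threshold decision threshold
#' @return a [PredictionSet-class]
#' @export
predictBaseline <- function(baseline, smiles, threshold = 0.5) {
  X <- .tokenCountMatrix(smiles, baseline$features)
  probs <- .sigmoid(cbind(1, X) %*% baseline$coefficients)
  dimnames(probs) <- list(NULL, baseline$labelOrder)
  predicted <- lapply(seq_along(smiles), function(i)
    baseline$labelOrder[probs[i, ] >= threshold])
  new("PredictionSet", smiles = as.character(smiles), probabilities = probs,
      threshold = threshold, predicted = predicted,
      itemErrors = data.frame(index = integer(), smiles = character(),
                              message = character()))
}
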
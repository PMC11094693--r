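#' Effective number of samples of a class
#'
#' The overlap-discounted size of a class with \code{n} members:
#' \deqn{E_n = (1 - \beta^n) / (1 - \beta),}
#' the expected coverage of \code{n} possibly overlapping unit volumes. It
#' grows monotonically from 1 (at n = 1) toward the saturation value
#' \eqn{1/(1-\beta)} as n grows, and never exceeds n. Larger \eqn{\beta}
#' means less discounting of additional members.
#'
#' @param n class size(s) |C|, integer >= 1 (vectorized)
#' @param beta overlap parameter in [0, 1)
#' @return numeric vector of effective numbers
#' @examples
#' effectiveNumber(1, 0.99)   # 1
#' effectiveNumber(2, 0.99)   # 1.99
#' @export
effectiveNumber <- function(n, beta) {
  if (any(n < 1)) stop("class size n must be >= 1")
  if (length(beta) != 1L || beta < 0 || beta >= 1) stop("beta must be in [0, 1)")
  if (beta == 0) return(rep(1, length(n)))
  # expm1/log for numerical stability at large n / beta near 1
  -expm1(n * log(beta)) / (1 - beta)
}

#' Class-balanced loss weights from member counts
#'
#' Each label class C receives the inverse of its effective number as loss
#' weight, \eqn{w_C = (1-\beta)/(1-\beta^{|C|})}: weights lie in
#' \eqn{(1-\beta, 1]} and strictly decrease as the member count grows, so
#' prediction errors on small classes cost more. No renormalization is
#' applied by default; \code{rescale = TRUE} rescales the weights to sum to
#' the number of classes (a variant some implementations of the weighting
#' use).
#'
#' @param memberCounts named integer vector, label CURIE -> |C| (>= 1), e.g.
#'   \code{memberCounts(selection)}
#' @param beta overlap parameter; 0.99 is the conventional choice
#' @param rescale rescale weights to sum to the class count
#' @return a [ClassWeights-class]
#' @export
classWeights <- function(memberCounts, beta = 0.99, rescale = FALSE) {
  if (is.null(names(memberCounts)) || any(!nzchar(names(memberCounts))))
    stop("memberCounts must be named by label CURIE")
  if (anyNA(memberCounts)) stop("missing member count")
  w <- 1 / effectiveNumber(as.numeric(memberCounts), beta)
  if (rescale) w <- w * length(w) / sum(w)
  new("ClassWeights", weights = setNames(w, names(memberCounts)),
      beta = beta, memberCounts = setNames(as.integer(memberCounts),
                                           names(memberCounts)))
}

#' @rdname ClassWeights-class
#' @param x a ClassWeights
#' @export
labelWeights <- function(x) x@weights

setMethod("show", "ClassWeights", function(object) {
  cat("ClassWeights over", length(object@weights), "labels (beta =",
      object@beta, ")\n  range:",
      signif(min(object@weights), 4), "-", signif(max(object@weights), 4), "\n")
})

#' Class-weighted multi-label binary cross-entropy
#'
#' Mean over molecules and labels of \eqn{w_j \,\mathrm{BCE}(p_{ij},
#' t_{ij})}. Probabilities are clamped to \code{[clamp, 1 - clamp]} before
#' the logarithm for numerical stability. With all weights equal to 1 this
#' is the ordinary mean binary cross-entropy.
#'
#' @param probabilities numeric matrix, molecules x labels, values in (0, 1)
#'   (column names must match the weights when given)
#' @param targets binary matrix of the same shape
#' @param weights a [ClassWeights-class], a named numeric vector, or NULL
#'   for unweighted loss
#' @param clamp clamping bound (default 1e-12)
#' @return non-negative scalar loss
#' @examples
#' p <- matrix(c(0.5, 0.5), 1); t <- matrix(c(1, 0), 1)
#' weightedMultilabelLoss(p, t, c(a = 1, b = 0.5))  # (1*log(2) + 0.5*log(2))/2
#' @export
weightedMultilabelLoss <- function(probabilities, targets, weights = NULL,
                                   clamp = 1e-12) {
  if (!all(dim(probabilities) == dim(targets)))
    stop("probabilities and targets must have the same shape")
  if (any(probabilities < 0 | probabilities > 1))
    stop("probabilities must lie in [0, 1]")
  w <- rep(1, ncol(probabilities))
  if (!is.null(weights)) {
    wv <- if (is(weights, "ClassWeights")) weights@weights else weights
    if (!is.null(colnames(probabilities)) && !is.null(names(wv))) {
      if (!all(colnames(probabilities) %in% names(wv)))
        stop("label order does not match weights")
      w <- unname(wv[colnames(probabilities)])
    } else {
      if (length(wv) != ncol(probabilities))
        stop("weights length must equal the number of labels")
      w <- unname(wv)
    }
  }
  p <- pmin(pmax(probabilities, clamp), 1 - clamp)
  bce <- -(targets * log(p) + (1 - targets) * log(1 - p))
  mean(sweep(bce, 2L, w, `*`))
}
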
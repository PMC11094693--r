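# From-scratch Transformer encoder: learned token + position embeddings,
# pre-norm blocks (LayerNorm -> multi-head self-attention -> residual;
# LayerNorm -> GELU feed-forward -> residual), final LayerNorm, sigmoid
# multi-label head read from the sequence-start (CLS) position. Forward and
# backward passes are hand-written base-R matrix code; Adam does the
# updates. Batches are stored sample-major as (B*T) x d matrices so the
# linear projections are single BLAS calls; only the T x T attention
# products loop over samples and heads.

#' Encoder configuration
#'
#' Hyperparameters of the Transformer multi-label classifier. The defaults
#' are desk-scale: they train the synthetic motif benchmark on one CPU in
#' well under a minute per run. All randomness (initialization, batch
#' shuffling, dropout) is driven by \code{seed}.
#'
#' @param layers number of encoder blocks
#' @param heads attention heads (must divide \code{embeddingDim})
#' @param embeddingDim model width d
#' @param ffnDim feed-forward hidden width (default 2 d)
#' @param maxLength encoded sequence length including the CLS position
#' @param dropout dropout probability in [0, 1)
#' @param learningRate Adam step size
#' @param epochs training epochs
#' @param batchSize minibatch size
#' @param seed integer RNG seed
#' @param patience epochs without validation improvement before stopping
#'   (Inf disables early stopping; the best-validation checkpoint is
#'   returned either way)
#' @param truncate truncate over-long sequences at encoding instead of
#'   failing
#' @return a named list
#' @export
encoderConfig <- function(layers = 2L, heads = 4L, embeddingDim = 32L,
                          ffnDim = 2L * embeddingDim, maxLength = 24L,
                          dropout = 0.1, learningRate = 3e-3, epochs = 20L,
                          batchSize = 64L, seed = 0L, patience = Inf,
                          truncate = FALSE) {
  stopifnot(layers >= 1, heads >= 1, embeddingDim >= 1,
            embeddingDim %% heads == 0, maxLength >= 2,
            dropout >= 0, dropout < 1, learningRate > 0, epochs >= 1,
            batchSize >= 1)
  list(layers = as.integer(layers), heads = as.integer(heads),
       embeddingDim = as.integer(embeddingDim), ffnDim = as.integer(ffnDim),
       maxLength = as.integer(maxLength), dropout = dropout,
       learningRate = learningRate, epochs = as.integer(epochs),
       batchSize = as.integer(batchSize), seed = as.integer(seed),
       patience = patience, truncate = isTRUE(truncate))
}

.LN_EPS <- 1e-5

.initParams <- function(config, vocabSize, nLabels) {
  d <- config$embeddingDim; f <- config$ffnDim
  sd0 <- 0.02
  mat <- function(nr, nc) matrix(rnorm(nr * nc, sd = sd0), nr, nc)
  p <- list(E = mat(vocabSize, d), P = mat(config$maxLength, d))
  for (l in seq_len(config$layers)) {
    pre <- paste0("L", l, ".")
    p[[paste0(pre, "ln1.g")]] <- rep(1, d); p[[paste0(pre, "ln1.b")]] <- rep(0, d)
    p[[paste0(pre, "Wq")]] <- mat(d, d); p[[paste0(pre, "Wk")]] <- mat(d, d)
    p[[paste0(pre, "Wv")]] <- mat(d, d); p[[paste0(pre, "Wo")]] <- mat(d, d)
    p[[paste0(pre, "ln2.g")]] <- rep(1, d); p[[paste0(pre, "ln2.b")]] <- rep(0, d)
    p[[paste0(pre, "W1")]] <- mat(d, f); p[[paste0(pre, "b1")]] <- rep(0, f)
    p[[paste0(pre, "W2")]] <- mat(f, d); p[[paste0(pre, "b2")]] <- rep(0, d)
  }
  p[["lnF.g"]] <- rep(1, d); p[["lnF.b"]] <- rep(0, d)
  p[["Wh"]] <- mat(d, nLabels); p[["bh"]] <- rep(0, nLabels)
  p
}

.lnForward <- function(x, g, b) {
  mu <- rowMeans(x)
  xc <- x - mu
  inv <- 1 / sqrt(rowMeans(xc * xc) + .LN_EPS)
  xhat <- xc * inv
  y <- xhat * rep(g, each = nrow(x)) + rep(b, each = nrow(x))
  list(y = y, xhat = xhat, inv = inv)
}

.lnBackward <- function(dy, cache, g) {
  n <- nrow(dy)
  dxhat <- dy * rep(g, each = n)
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * cache$xhat)
  dx <- cache$inv * (dxhat - m1 - cache$xhat * m2)
  list(dx = dx, dg = colSums(dy * cache$xhat), db = colSums(dy))
}

.geluForward <- function(x) {
  c0 <- sqrt(2 / pi)
  th <- tanh(c0 * (x + 0.044715 * x^3))
  list(y = 0.5 * x * (1 + th), th = th)
}

.geluBackward <- function(dy, x, th) {
  c0 <- sqrt(2 / pi)
  dy * (0.5 * (1 + th) + 0.5 * x * (1 - th^2) * c0 * (1 + 3 * 0.044715 * x^2))
}

# Xflat: (B*T) 0-based token indices, sample-major; lens: valid length per
# sample (CLS included). Returns logits (B x C) and, when requested, the
# caches needed for backward / the attention maps.
.forwardBatch <- function(params, config, Xflat, lens, training = FALSE,
                          keepCache = training, storeAttention = FALSE) {
  T <- config$maxLength; d <- config$embeddingDim
  H <- config$heads; dh <- d %/% H
  B <- length(lens)
  drop <- if (training) config$dropout else 0
  Hc <- params$E[Xflat + 1L, , drop = FALSE] +
    params$P[rep(seq_len(T), B), , drop = FALSE]
  keyMask <- matrix(rep(seq_len(T), B), nrow = B, byrow = TRUE) <=
    matrix(lens, nrow = B, ncol = T)
  layerCaches <- vector("list", config$layers)
  attn <- if (storeAttention) vector("list", config$layers)
  for (l in seq_len(config$layers)) {
    pre <- paste0("L", l, ".")
    ln1 <- .lnForward(Hc, params[[paste0(pre, "ln1.g")]], params[[paste0(pre, "ln1.b")]])
    Q <- ln1$y %*% params[[paste0(pre, "Wq")]]
    K <- ln1$y %*% params[[paste0(pre, "Wk")]]
    V <- ln1$y %*% params[[paste0(pre, "Wv")]]
    Ctx <- matrix(0, nrow(Hc), d)
    A <- vector("list", B)
    for (b in seq_len(B)) {
      rb <- ((b - 1L) * T + 1L):(b * T)
      mk <- keyMask[b, ]
      Ab <- vector("list", H)
      for (h in seq_len(H)) {
        ch <- ((h - 1L) * dh + 1L):(h * dh)
        S <- tcrossprod(Q[rb, ch, drop = FALSE], K[rb, ch, drop = FALSE]) / sqrt(dh)
        S[, !mk] <- -Inf
        rmax <- S[cbind(seq_len(T), max.col(S, ties.method = "first"))]
        eS <- exp(S - rmax)
        Ah <- eS / rowSums(eS)
        Ctx[rb, ch] <- Ah %*% V[rb, ch, drop = FALSE]
        Ab[[h]] <- Ah
      }
      A[[b]] <- Ab
    }
    O <- Ctx %*% params[[paste0(pre, "Wo")]]
    M1 <- NULL
    if (drop > 0) {
      M1 <- matrix(runif(length(O)) >= drop, nrow(O)) / (1 - drop)
      O <- O * M1
    }
    Hmid <- Hc + O
    ln2 <- .lnForward(Hmid, params[[paste0(pre, "ln2.g")]], params[[paste0(pre, "ln2.b")]])
    U <- ln2$y %*% params[[paste0(pre, "W1")]] +
      rep(params[[paste0(pre, "b1")]], each = nrow(Hmid))
    ge <- .geluForward(U)
    Fo <- ge$y %*% params[[paste0(pre, "W2")]] +
      rep(params[[paste0(pre, "b2")]], each = nrow(Hmid))
    M2 <- NULL
    if (drop > 0) {
      M2 <- matrix(runif(length(Fo)) >= drop, nrow(Fo)) / (1 - drop)
      Fo <- Fo * M2
    }
    Hnew <- Hmid + Fo
    if (keepCache)
      layerCaches[[l]] <- list(ln1 = ln1, Q = Q, K = K, V = V, A = A, Ctx = Ctx,
                               M1 = M1, Hmid = Hmid, ln2 = ln2, U = U, ge = ge,
                               M2 = M2)
    if (storeAttention) attn[[l]] <- A
    Hc <- Hnew
  }
  lnF <- .lnForward(Hc, params$lnF.g, params$lnF.b)
  clsRows <- seq(1L, B * T, by = T)
  logits <- lnF$y[clsRows, , drop = FALSE] %*% params$Wh +
    rep(params$bh, each = B)
  out <- list(logits = logits)
  if (keepCache)
    out$cache <- list(layers = layerCaches, lnF = lnF, clsRows = clsRows,
                      Xflat = Xflat, keyMask = keyMask, B = B, Hfinal = Hc)
  if (storeAttention) out$attention <- attn
  out
}

.backwardBatch <- function(params, config, cache, dLogits) {
  T <- config$maxLength; d <- config$embeddingDim
  H <- config$heads; dh <- d %/% H
  B <- cache$B
  grads <- list()
  grads$Wh <- crossprod(cache$lnF$y[cache$clsRows, , drop = FALSE], dLogits)
  grads$bh <- colSums(dLogits)
  dHF <- matrix(0, B * T, d)
  dHF[cache$clsRows, ] <- dLogits %*% t(params$Wh)
  bF <- .lnBackward(dHF, cache$lnF, params$lnF.g)
  grads$lnF.g <- bF$dg; grads$lnF.b <- bF$db
  dH <- bF$dx
  for (l in rev(seq_len(config$layers))) {
    pre <- paste0("L", l, ".")
    cl <- cache$layers[[l]]
    dFo <- dH
    if (!is.null(cl$M2)) dFo <- dFo * cl$M2
    grads[[paste0(pre, "W2")]] <- crossprod(cl$ge$y, dFo)
    grads[[paste0(pre, "b2")]] <- colSums(dFo)
    dG <- dFo %*% t(params[[paste0(pre, "W2")]])
    dU <- .geluBackward(dG, cl$U, cl$ge$th)
    grads[[paste0(pre, "W1")]] <- crossprod(cl$ln2$y, dU)
    grads[[paste0(pre, "b1")]] <- colSums(dU)
    dLn2y <- dU %*% t(params[[paste0(pre, "W1")]])
    b2 <- .lnBackward(dLn2y, cl$ln2, params[[paste0(pre, "ln2.g")]])
    grads[[paste0(pre, "ln2.g")]] <- b2$dg
    grads[[paste0(pre, "ln2.b")]] <- b2$db
    dHmid <- dH + b2$dx
    dO <- dHmid
    if (!is.null(cl$M1)) dO <- dO * cl$M1
    grads[[paste0(pre, "Wo")]] <- crossprod(cl$Ctx, dO)
    dCtx <- dO %*% t(params[[paste0(pre, "Wo")]])
    dQ <- matrix(0, B * T, d); dK <- matrix(0, B * T, d); dV <- matrix(0, B * T, d)
    for (b in seq_len(B)) {
      rb <- ((b - 1L) * T + 1L):(b * T)
      for (h in seq_len(H)) {
        ch <- ((h - 1L) * dh + 1L):(h * dh)
        Ah <- cl$A[[b]][[h]]
        dCh <- dCtx[rb, ch, drop = FALSE]
        dA <- tcrossprod(dCh, cl$V[rb, ch, drop = FALSE])
        dV[rb, ch] <- dV[rb, ch] + crossprod(Ah, dCh)
        dS <- Ah * (dA - rowSums(dA * Ah))
        dQ[rb, ch] <- dS %*% cl$K[rb, ch, drop = FALSE] / sqrt(dh)
        dK[rb, ch] <- crossprod(dS, cl$Q[rb, ch, drop = FALSE]) / sqrt(dh)
      }
    }
    grads[[paste0(pre, "Wq")]] <- crossprod(cl$ln1$y, dQ)
    grads[[paste0(pre, "Wk")]] <- crossprod(cl$ln1$y, dK)
    grads[[paste0(pre, "Wv")]] <- crossprod(cl$ln1$y, dV)
    dLn1y <- dQ %*% t(params[[paste0(pre, "Wq")]]) +
      dK %*% t(params[[paste0(pre, "Wk")]]) +
      dV %*% t(params[[paste0(pre, "Wv")]])
    b1 <- .lnBackward(dLn1y, cl$ln1, params[[paste0(pre, "ln1.g")]])
    grads[[paste0(pre, "ln1.g")]] <- b1$dg
    grads[[paste0(pre, "ln1.b")]] <- b1$db
    dH <- dHmid + b1$dx
  }
  # embeddings: fold (B*T) x d gradients back onto token and position rows
  tokGrad <- rowsum(dH, group = cache$Xflat, reorder = FALSE)
  dE <- matrix(0, nrow(params$E), d)
  dE[as.integer(rownames(tokGrad)) + 1L, ] <- tokGrad
  grads$E <- dE
  grads$P <- rowsum(dH, group = rep(seq_len(T), B), reorder = TRUE)
  grads
}

.adamInit <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

.adamStep <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t; c2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / c1) / (sqrt(state$v[[nm]] / c2) + eps)
  }
  list(params = params, state = state)
}
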
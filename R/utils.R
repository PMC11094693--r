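# Internal helpers shared across modules.

# Locale-independent lexicographic sort (C collation via radix method), so
# label order is identical on every machine.
.lexSort <- function(x) sort(x, method = "radix")

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
.withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

# Small deterministic sub-seed derivation (kept well below 2^31).
.subSeed <- function(seed, offset) {
  as.integer((as.double(seed) * 7919 + offset) %% 2147483647)
}

.hashCharacter <- function(x) {
  # order-sensitive polynomial rolling hash (mod a Mersenne prime)
  bytes <- utf8ToInt(paste(x, collapse = "\x1f"))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

# Kahn topological check over child->parent edges; returns NULL if acyclic,
# otherwise one cycle as a character vector of ids.
.findCycle <- function(ids, parents) {
  n <- length(ids)
  if (n == 0L) return(NULL)
  pidx <- lapply(parents, function(p) match(p, ids))
  outdeg <- lengths(pidx)                 # edges still pointing to parents
  children <- vector("list", n)           # reverse adjacency
  for (i in seq_len(n)) for (p in pidx[[i]]) children[[p]] <- c(children[[p]], i)
  queue <- which(outdeg == 0L)
  seen <- 0L
  while (length(queue)) {
    v <- queue[[1L]]; queue <- queue[-1L]
    seen <- seen + 1L
    for (c in children[[v]]) {
      outdeg[c] <- outdeg[c] - 1L
      if (outdeg[c] == 0L) queue <- c(queue, c)
    }
  }
  if (seen == n) return(NULL)
  # walk inside the residual subgraph until a vertex repeats
  residual <- which(outdeg > 0L)
  v <- residual[[1L]]
  path <- integer()
  while (!(v %in% path)) {
    path <- c(path, v)
    v <- intersect(pidx[[v]], residual)[[1L]]
  }
  cyc <- c(path[which(path == v):length(path)], v)
  ids[cyc]
}

# Topological order of all classes, parents before children.
.topoOrder <- function(ids, parentIdx) {
  n <- length(ids)
  outdeg <- lengths(parentIdx)
  children <- vector("list", n)
  for (i in seq_len(n)) for (p in parentIdx[[i]]) children[[p]] <- c(children[[p]], i)
  queue <- which(outdeg == 0L)
  order <- integer(0)
  while (length(queue)) {
    v <- queue[[1L]]; queue <- queue[-1L]
    order <- c(order, v)
    for (c in children[[v]]) {
      outdeg[c] <- outdeg[c] - 1L
      if (outdeg[c] == 0L) queue <- c(queue, c)
    }
  }
  if (length(order) != n) stop("graph is not acyclic")
  order
}

.sigmoid <- function(x) 1 / (1 + exp(-x))

# Per-molecule F1 between predicted and true binary rows; both-empty rows
# score 1 (a molecule with nothing to predict, predicted as such, is perfect).
.setF1 <- function(pred, truth) {
  tp <- sum(pred & truth); fp <- sum(pred & !truth); fn <- sum(!pred & truth)
  if (tp + fp + fn == 0L) return(1)
  2 * tp / (2 * tp + fp + fn)
}
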
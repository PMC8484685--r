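# Minimal CNN engine: batched im2col convolution, ReLU, global average
# pooling, dense layers, inverted dropout, class-weighted softmax
# cross-entropy, and Adam. Written for small (desk-scale) networks; all
# tensors are numeric arrays [h, w, c, n] and all randomness flows through
# R's RNG so runs are reproducible given a seed.

# ---- im2col geometry (memoized per model) ----

#' @keywords internal
im2colIndex <- function(H, W, C, k, s, p, env) {
  key <- paste("g", H, W, C, k, s, p, sep = "_")
  if (!is.null(env[[key]])) return(env[[key]])
  Hp <- H + 2L * p; Wp <- W + 2L * p
  oh <- (Hp - k) %/% s + 1L; ow <- (Wp - k) %/% s + 1L
  oyv <- rep(seq_len(oh), times = ow)
  oxv <- rep(seq_len(ow), each = oh)
  y0 <- (oyv - 1L) * s
  x0 <- (oxv - 1L) * s
  kyv <- rep(seq_len(k), times = k * C)
  kxv <- rep(rep(seq_len(k), each = k), times = C)
  cv <- rep(seq_len(C), each = k * k)
  idx <- outer(kyv, y0, "+") + outer(kxv - 1L, x0, "+") * Hp +
    (cv - 1L) * (Hp * Wp)
  # scatter operator for the backward pass: accumulates column entries of
  # the im2col matrix back onto padded-image positions
  scatter <- Matrix::sparseMatrix(i = as.integer(idx),
                                  j = seq_along(idx), x = 1,
                                  dims = c(Hp * Wp * C, length(idx)))
  g <- list(idx = idx, oh = oh, ow = ow, Hp = Hp, Wp = Wp,
            R = k * k * C, Tn = oh * ow, scatter = scatter)
  env[[key]] <- g
  g
}

#' @keywords internal
padBatch <- function(x, p) {
  if (p == 0L) return(x)
  d <- dim(x)
  xp <- array(0, c(d[1] + 2L * p, d[2] + 2L * p, d[3], d[4]))
  xp[(p + 1):(p + d[1]), (p + 1):(p + d[2]), , ] <- x
  xp
}

# ---- layer primitives (forward returns a cache for backward) ----

#' @keywords internal
convF <- function(x, W, b, k, s, p, genv) {
  d <- dim(x)
  g <- im2colIndex(d[1], d[2], d[3], k, s, p, genv)
  xp <- padBatch(x, p)
  n <- d[4]
  bkey <- paste("b", d[1], d[2], d[3], k, s, p, n, sep = "_")
  bigidx <- genv[[bkey]]
  if (is.null(bigidx)) {
    stride <- g$Hp * g$Wp * d[3]
    bigidx <- rep(as.vector(g$idx), times = n) +
      rep((seq_len(n) - 1L) * stride, each = g$R * g$Tn)
    genv[[bkey]] <- bigidx
  }
  Xcol <- xp[bigidx]
  dim(Xcol) <- c(g$R, g$Tn * n)
  Y <- W %*% Xcol + b
  dim(Y) <- c(nrow(W), g$oh, g$ow, n)
  y <- aperm(Y, c(2, 3, 1, 4))
  list(y = y, cache = list(Xcol = Xcol, bigidx = bigidx, dimx = d, g = g,
                           W = W, k = k, s = s, p = p))
}

#' @keywords internal
convB <- function(dy, cache) {
  g <- cache$g; d <- cache$dimx; n <- d[4]
  dY <- aperm(dy, c(3, 1, 2, 4))
  dim(dY) <- c(dim(dy)[3], g$oh * g$ow * n)
  dW <- tcrossprod(dY, cache$Xcol)
  db <- rowSums(dY)
  dXcol <- crossprod(cache$W, dY)
  dxp <- as.matrix(g$scatter %*% matrix(dXcol, g$R * g$Tn, n))
  dxp <- array(dxp, c(g$Hp, g$Wp, d[3], n))
  p <- cache$p
  dx <- if (p > 0L) dxp[(p + 1):(p + d[1]), (p + 1):(p + d[2]), , , drop = FALSE]
        else dxp
  list(dx = dx, dW = dW, db = db)
}

# Batch normalization over (h, w, n) per channel, without affine
# parameters (the compact branches are small enough that the following
# convolution absorbs scale). Training mode normalizes by batch statistics
# and exponentially updates the running buffers used in evaluation mode.
#' @keywords internal
bnF <- function(x, rmean, rvar, train, momentum = 0.9, eps = 1e-3) {
  d <- dim(x)
  C <- d[3]
  xm <- matrix(aperm(x, c(1, 2, 4, 3)), d[1] * d[2] * d[4], C)
  if (train) {
    mu <- colMeans(xm)
    xc <- sweep(xm, 2, mu)
    va <- colMeans(xc * xc)
    newMean <- momentum * rmean + (1 - momentum) * mu
    newVar <- momentum * rvar + (1 - momentum) * va
  } else {
    mu <- rmean; va <- rvar
    xc <- sweep(xm, 2, mu)
    newMean <- rmean; newVar <- rvar
  }
  istd <- 1 / sqrt(va + eps)
  ym <- sweep(xc, 2, istd, "*")
  y <- aperm(array(ym, c(d[1], d[2], d[4], C)), c(1, 2, 4, 3))
  list(y = y, cache = list(xc = xc, istd = istd, d = d, train = train),
       newMean = newMean, newVar = newVar)
}

#' @keywords internal
bnB <- function(dy, cache) {
  d <- cache$d
  C <- d[3]
  N <- d[1] * d[2] * d[4]
  dym <- matrix(aperm(dy, c(1, 2, 4, 3)), N, C)
  if (!cache$train) {
    dxm <- sweep(dym, 2, cache$istd, "*")
  } else {
    xhat <- sweep(cache$xc, 2, cache$istd, "*")
    s1 <- colMeans(dym)
    s2 <- colMeans(dym * xhat)
    dxm <- sweep(dym, 2, s1) - sweep(xhat, 2, s2, "*")
    dxm <- sweep(dxm, 2, cache$istd, "*")
  }
  aperm(array(dxm, c(d[1], d[2], d[4], C)), c(1, 2, 4, 3))
}

#' @keywords internal
reluF <- function(x) {
  y <- x; y[y < 0] <- 0
  list(y = y, cache = x > 0)
}

#' @keywords internal
reluB <- function(dy, cache) dy * cache

#' @keywords internal
gapF <- function(x) {
  d <- dim(x)
  y <- apply(x, c(3, 4), mean)           # [C, N]
  list(y = matrix(y, d[3], d[4]), cache = d)
}

#' @keywords internal
gapB <- function(dy, d) {
  sc <- 1 / (d[1] * d[2])
  array(rep(as.vector(dy), each = d[1] * d[2]) * sc, d)
}

#' @keywords internal
denseF <- function(x, W, b) {
  list(y = W %*% x + b, cache = list(x = x, W = W))
}

#' @keywords internal
denseB <- function(dy, cache) {
  list(dx = t(cache$W) %*% dy, dW = dy %*% t(cache$x), db = rowSums(dy))
}

# Inverted dropout on feature vectors [F, N]; at keep rate q, surviving
# units are scaled by 1/q so evaluation mode is the identity.
#' @keywords internal
dropoutF <- function(x, keep, train) {
  if (!train || keep >= 1) return(list(y = x, cache = NULL))
  m <- matrix(rbinom(length(x), 1L, keep), nrow(x), ncol(x)) / keep
  list(y = x * m, cache = m)
}

#' @keywords internal
dropoutB <- function(dy, cache) if (is.null(cache)) dy else dy * cache

# Class-weighted softmax cross-entropy. `labels` in 1..K; per-sample weight
# w[labels]; loss = mean_i w_i * CE_i; gradient matches.
#' @keywords internal
softmaxCE <- function(logits, labels, weights = NULL) {
  K <- nrow(logits); n <- ncol(logits)
  m <- apply(logits, 2, max)
  z <- exp(sweep(logits, 2, m))
  pr <- sweep(z, 2, colSums(z), "/")
  if (is.null(weights)) weights <- rep(1, K)
  wi <- weights[labels]
  pick <- pr[cbind(labels, seq_len(n))]
  loss <- mean(wi * (-log(pmax(pick, 1e-12))))
  dlog <- pr
  dlog[cbind(labels, seq_len(n))] <- dlog[cbind(labels, seq_len(n))] - 1
  dlog <- sweep(dlog, 2, wi, "*") / n
  list(loss = loss, dlogits = dlog, probs = pr)
}

#' @keywords internal
softmaxProbs <- function(logits) {
  m <- apply(logits, 2, max)
  z <- exp(sweep(logits, 2, m))
  sweep(z, 2, colSums(z), "/")
}

# ---- parameter initialization and Adam ----

# He-normal initialization for a conv/dense weight of shape [fanOut, fanIn].
#' @keywords internal
heInit <- function(fanOut, fanIn) {
  matrix(rnorm(fanOut * fanIn, sd = sqrt(2 / fanIn)), fanOut, fanIn)
}

#' @keywords internal
adamInit <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

#' @keywords internal
adamStep <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    gr <- grads[[nm]]
    if (is.null(gr)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gr
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gr * gr
    mh <- state$m[[nm]] / bc1
    vh <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mh / (sqrt(vh) + eps)
  }
  list(params = params, state = state)
}

#' @keywords internal
accumGrad <- function(grads, nm, g) {
  grads[[nm]] <- if (is.null(grads[[nm]])) g else grads[[nm]] + g
  grads
}
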
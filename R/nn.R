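# Dense-layer, layer-norm and attention primitives with explicit backward
# passes. All activations are row-major: X is (positions x features).
# Gradients are accumulated into an environment keyed by parameter name so
# that a whole forward cache can be walked backwards without copying.

lin_fwd <- function(X, W, b) {
  Y <- X %*% W
  Y + matrix(b, nrow(Y), length(b), byrow = TRUE)
}

# returns dX; accumulates dW, db into gr under names nW, nb
lin_bwd <- function(dY, X, W, gr, nW, nb) {
  if (need_g(gr, nW)) addg(gr, nW, crossprod(X, dY))
  if (need_g(gr, nb)) addg(gr, nb, colSums(dY))
  dY %*% t(W)
}

relu <- function(x) pmax(x, 0)

addg <- function(gr, name, value) {
  if (is.null(gr[[name]])) gr[[name]] <- value else gr[[name]] <- gr[[name]] + value
  invisible(NULL)
}

# When the gradient environment carries a trainable-flag vector under `.tr`,
# weight gradients of frozen parameters are skipped (their matmuls dominate
# backward cost when most of the model is frozen).
need_g <- function(gr, nm) {
  tr <- gr[[".tr"]]
  is.null(tr) || isTRUE(unname(tr[nm]))
}

ln_fwd <- function(X, g, b, eps = 1e-5) {
  mu <- rowMeans(X)
  xc <- X - mu
  v <- rowMeans(xc * xc)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  Y <- xhat * matrix(g, nrow(X), length(g), byrow = TRUE) +
    matrix(b, nrow(X), length(b), byrow = TRUE)
  list(Y = Y, xhat = xhat, inv = inv)
}

ln_bwd <- function(dY, cache, g, gr, ng, nb) {
  xhat <- cache$xhat
  if (need_g(gr, ng)) addg(gr, ng, colSums(dY * xhat))
  if (need_g(gr, nb)) addg(gr, nb, colSums(dY))
  dxhat <- dY * matrix(g, nrow(dY), length(g), byrow = TRUE)
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  cache$inv * (dxhat - m1 - xhat * m2)
}

softmax_rows <- function(S) {
  m <- S[cbind(seq_len(nrow(S)), max.col(S, ties.method = "first"))]
  E <- exp(S - m)
  E / rowSums(E)
}

# ---- multi-head self-attention -------------------------------------------

# p: list with Wq,bq,Wk,bk,Wv,bv,Wo,bo (each W d x d); lora: NULL or list
# with per-target A (d x r), B (r x d) and scale alpha/r; kmask: logical
# vector of attendable (non-PAD) key positions.
attn_fwd <- function(X, p, n_heads, kmask = NULL, lora = NULL) {
  d <- ncol(X)
  dh <- d %/% n_heads
  lora_arm <- function(Y, tgt, X) {
    if (is.null(lora) || is.null(lora[[tgt]])) return(list(Y = Y, mid = NULL))
    mid <- X %*% lora[[tgt]]$A
    list(Y = Y + lora$scale * (mid %*% lora[[tgt]]$B), mid = mid)
  }
  q0 <- lin_fwd(X, p$Wq, p$bq); qa <- lora_arm(q0, "query", X)
  k0 <- lin_fwd(X, p$Wk, p$bk); ka <- lora_arm(k0, "key", X)
  v0 <- lin_fwd(X, p$Wv, p$bv); va <- lora_arm(v0, "value", X)
  Q <- qa$Y; K <- ka$Y; V <- va$Y
  n <- nrow(X)
  O <- matrix(0, n, d)
  Ps <- vector("list", n_heads)
  for (h in seq_len(n_heads)) {
    idx <- ((h - 1) * dh + 1):(h * dh)
    S <- tcrossprod(Q[, idx, drop = FALSE], K[, idx, drop = FALSE]) / sqrt(dh)
    if (!is.null(kmask) && !all(kmask)) S[, !kmask] <- -Inf
    Pm <- softmax_rows(S)
    Ps[[h]] <- Pm
    O[, idx] <- Pm %*% V[, idx, drop = FALSE]
  }
  o0 <- lin_fwd(O, p$Wo, p$bo); oa <- lora_arm(o0, "output", O)
  list(Y = oa$Y,
       cache = list(X = X, Q = Q, K = K, V = V, O = O, Ps = Ps,
                    mids = list(query = qa$mid, key = ka$mid,
                                value = va$mid, output = oa$mid)))
}

attn_bwd <- function(dY, cache, p, n_heads, gr, prefix, lora = NULL,
                     lora_prefix = NULL) {
  X <- cache$X; O <- cache$O
  d <- ncol(X); dh <- d %/% n_heads
  lora_bwd <- function(dOut, tgt, Xin, mid) {
    if (is.null(lora) || is.null(lora[[tgt]])) return(NULL)
    s <- lora$scale
    nB <- paste0(lora_prefix, tgt, ".B")
    nA <- paste0(lora_prefix, tgt, ".A")
    if (need_g(gr, nB)) addg(gr, nB, s * crossprod(mid, dOut))
    dmid <- s * (dOut %*% t(lora[[tgt]]$B))
    if (need_g(gr, nA)) addg(gr, nA, crossprod(Xin, dmid))
    dmid %*% t(lora[[tgt]]$A)
  }
  dO <- lin_bwd(dY, O, p$Wo, gr, paste0(prefix, "Wo"), paste0(prefix, "bo"))
  extra <- lora_bwd(dY, "output", O, cache$mids$output)
  if (!is.null(extra)) dO <- dO + extra
  dQ <- matrix(0, nrow(X), d); dK <- dQ; dV <- dQ
  for (h in seq_len(n_heads)) {
    idx <- ((h - 1) * dh + 1):(h * dh)
    Pm <- cache$Ps[[h]]
    dOh <- dO[, idx, drop = FALSE]
    dV[, idx] <- crossprod(Pm, dOh)
    dP <- tcrossprod(dOh, cache$V[, idx, drop = FALSE])
    dS <- Pm * (dP - rowSums(dP * Pm))
    dQ[, idx] <- dS %*% cache$K[, idx, drop = FALSE] / sqrt(dh)
    dK[, idx] <- crossprod(dS, cache$Q[, idx, drop = FALSE]) / sqrt(dh)
  }
  dX <- lin_bwd(dQ, X, p$Wq, gr, paste0(prefix, "Wq"), paste0(prefix, "bq"))
  extra <- lora_bwd(dQ, "query", X, cache$mids$query)
  if (!is.null(extra)) dX <- dX + extra
  dX <- dX + lin_bwd(dK, X, p$Wk, gr, paste0(prefix, "Wk"), paste0(prefix, "bk"))
  extra <- lora_bwd(dK, "key", X, cache$mids$key)
  if (!is.null(extra)) dX <- dX + extra
  dX <- dX + lin_bwd(dV, X, p$Wv, gr, paste0(prefix, "Wv"), paste0(prefix, "bv"))
  extra <- lora_bwd(dV, "value", X, cache$mids$value)
  if (!is.null(extra)) dX <- dX + extra
  dX
}

# ---- bottleneck adapter (matrix form, row-major) -------------------------

ad_fwd <- function(X, Wd, bd, Wu, bu) {
  pre <- lin_fwd(X, Wd, bd)
  hid <- relu(pre)
  list(Y = lin_fwd(hid, Wu, bu), pre = pre, hid = hid, X = X)
}

ad_bwd <- function(dY, cache, Wd, Wu, gr, prefix) {
  dhid <- lin_bwd(dY, cache$hid, Wu, gr, paste0(prefix, "Wu"),
                  paste0(prefix, "bu"))
  dpre <- dhid * (cache$pre > 0)
  lin_bwd(dpre, cache$X, Wd, gr, paste0(prefix, "Wd"), paste0(prefix, "bd"))
}
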
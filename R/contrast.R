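# Multi-view NT-Xent-style contrastive loss over paired sequence/structure
# projections. For protein i the per-pair loss is
#   -log[ exp(sim(s_i, c_i)/tau) / D_i ],
# where D_i sums, over k != i, the cross-modal repulsion exp(sim(s_i,c_k)/tau)
# and the two intra-modal repulsions exp(sim(s_i,s_k)/tau) and
# exp(sim(c_i,c_k)/tau). As typeset, the positive pair is excluded from the
# denominator; `include_positive_in_denominator = TRUE` switches to the
# standard NT-Xent variant that adds it.

#' Cosine similarity
#'
#' `sim(x, y) = x . y / (||x|| ||y||)`; symmetric and invariant to positive
#' rescaling of either argument.
#'
#' @param x,y Nonzero numeric vectors of equal length.
#' @return Scalar in `[-1, 1]`.
#' @export
cosine_sim <- function(x, y) {
  nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) stop("cosine_sim: zero vector")
  sum(x * y) / (nx * ny)
}

normalize_rows <- function(M) {
  n <- sqrt(rowSums(M^2))
  if (any(n == 0)) stop("zero row in embedding matrix")
  list(U = M / n, norms = n)
}

# log(sum(exp(v))) with max subtraction
lse <- function(v) {
  m <- max(v)
  m + log(sum(exp(v - m)))
}

#' Multi-view contrastive loss
#'
#' Computes the per-protein contrastive losses and their batch mean for a
#' batch of paired 256-d sequence/structure projections (rows aligned by
#' protein). Numerically stabilized via log-sum-exp.
#'
#' @param seq_proj,str_proj `N x p` matrices of projected embeddings, row
#'   `i` of both referring to the same protein; `N >= 2`.
#' @param tau Temperature (> 0); default 0.05.
#' @param include_positive_in_denominator Add the positive-pair term to the
#'   denominator (standard NT-Xent variant). Default `FALSE` (literal
#'   three-term form).
#' @return A `loss_breakdown`: list with `per_pair` (length-`N` vector) and
#'   `batch_loss` (their mean).
#' @export
multiview_loss <- function(seq_proj, str_proj, tau = 0.05,
                           include_positive_in_denominator = FALSE) {
  seq_proj <- as.matrix(seq_proj); str_proj <- as.matrix(str_proj)
  N <- nrow(seq_proj)
  stopifnot(nrow(str_proj) == N, ncol(str_proj) == ncol(seq_proj))
  if (N < 2L)
    stop("multiview_loss: batch size must be >= 2 (empty denominator at N = 1)")
  if (tau <= 0) stop("multiview_loss: tau must be positive")
  U <- normalize_rows(seq_proj)$U
  V <- normalize_rows(str_proj)$U
  Ssc <- tcrossprod(U, V) / tau   # sim(s_i, c_k)/tau
  Sss <- tcrossprod(U, U) / tau
  Scc <- tcrossprod(V, V) / tau
  per <- numeric(N)
  for (i in seq_len(N)) {
    terms <- c(Ssc[i, -i], Sss[i, -i], Scc[i, -i])
    if (include_positive_in_denominator) terms <- c(terms, Ssc[i, i])
    per[i] <- -Ssc[i, i] + lse(terms)
  }
  structure(list(per_pair = per, batch_loss = mean(per)),
            class = "loss_breakdown")
}

#' @export
print.loss_breakdown <- function(x, ...) {
  cat("<loss_breakdown> batch_loss =", format(x$batch_loss),
      "over", length(x$per_pair), "pairs\n")
  invisible(x)
}

#' Analytic gradient of the multi-view contrastive loss
#'
#' Gradient of `batch_loss` with respect to both (unnormalized) projection
#' matrices; the workhorse of the pretraining loop, validated against
#' central finite differences by [loss_gradient_check()].
#'
#' @inheritParams multiview_loss
#' @return List with `loss`, `per_pair`, `d_seq`, `d_str`.
#' @export
multiview_loss_grad <- function(seq_proj, str_proj, tau = 0.05,
                                include_positive_in_denominator = FALSE) {
  seq_proj <- as.matrix(seq_proj); str_proj <- as.matrix(str_proj)
  N <- nrow(seq_proj)
  stopifnot(N >= 2L, tau > 0)
  nu <- normalize_rows(seq_proj); nv <- normalize_rows(str_proj)
  U <- nu$U; V <- nv$U
  Ssc <- tcrossprod(U, V) / tau
  Sss <- tcrossprod(U, U) / tau
  Scc <- tcrossprod(V, V) / tau
  per <- numeric(N)
  # weight matrices: dL_i / d(sim/tau) entries, excluding the 1/N batch mean
  Wsc <- matrix(0, N, N); Wss <- matrix(0, N, N); Wcc <- matrix(0, N, N)
  for (i in seq_len(N)) {
    terms <- c(Ssc[i, -i], Sss[i, -i], Scc[i, -i])
    if (include_positive_in_denominator) terms <- c(terms, Ssc[i, i])
    logD <- lse(terms)
    per[i] <- -Ssc[i, i] + logD
    Wsc[i, -i] <- exp(Ssc[i, -i] - logD)
    Wss[i, -i] <- exp(Sss[i, -i] - logD)
    Wcc[i, -i] <- exp(Scc[i, -i] - logD)
    Wsc[i, i] <- -1 +
      if (include_positive_in_denominator) exp(Ssc[i, i] - logD) else 0
  }
  sc <- 1 / (N * tau)   # batch mean and the /tau inside the exponents
  Gsc <- Wsc * sc; Gss <- Wss * sc; Gcc <- Wcc * sc
  dU <- Gsc %*% V + (Gss + t(Gss)) %*% U
  dV <- crossprod(Gsc, U) + (Gcc + t(Gcc)) %*% V
  # through row normalization u = s / ||s||
  unproject <- function(dU, U, norms) {
    (dU - U * rowSums(dU * U)) / norms
  }
  list(loss = mean(per), per_pair = per,
       d_seq = unproject(dU, U, nu$norms),
       d_str = unproject(dV, V, nv$norms))
}

#' Finite-difference check of the contrastive-loss gradient
#'
#' Compares the analytic gradient of the batch loss with central finite
#' differences over every coordinate of both projection matrices and returns
#' the largest scaled deviation `|analytic - numeric| / (1 + max(|.|))`.
#'
#' @param seq_proj,str_proj Batch matrices as in [multiview_loss()].
#' @param tau Temperature.
#' @param include_positive_in_denominator Denominator variant flag.
#' @param h Step size for the central differences.
#' @return Maximum scaled gradient error (scalar).
#' @export
loss_gradient_check <- function(seq_proj, str_proj, tau = 0.05,
                                include_positive_in_denominator = FALSE,
                                h = 1e-5) {
  an <- multiview_loss_grad(seq_proj, str_proj, tau,
                            include_positive_in_denominator)
  f <- function(S, C) multiview_loss(S, C, tau,
                                     include_positive_in_denominator)$batch_loss
  maxerr <- 0
  for (mat in c("seq", "str")) {
    M <- if (mat == "seq") seq_proj else str_proj
    G <- if (mat == "seq") an$d_seq else an$d_str
    for (idx in seq_along(M)) {
      Mp <- M; Mp[idx] <- Mp[idx] + h
      Mm <- M; Mm[idx] <- Mm[idx] - h
      num <- if (mat == "seq") (f(Mp, str_proj) - f(Mm, str_proj)) / (2 * h)
             else (f(seq_proj, Mp) - f(seq_proj, Mm)) / (2 * h)
      err <- abs(G[idx] - num) / (1 + max(abs(G[idx]), abs(num)))
      if (err > maxerr) maxerr <- err
    }
  }
  maxerr
}
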
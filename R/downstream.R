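# Downstream supervised heads: a single dense classification layer per task,
# focal loss (multiclass) or binary cross-entropy (multilabel), protein- or
# residue-level, with Fmax and residue accuracy as metrics.

#' Task head specification
#'
#' Presets mirror the reference task set: fold (protein-level, 1195 classes,
#' focal loss), reaction (384, focal), GO BP/MF/CC (1943/489/320,
#' multilabel BCE), EC (538, BCE) -- all truncated at 512 residues -- and
#' secondary structure (residue-level, 3 classes, focal, truncated at 1022).
#'
#' @param task One of `"fold"`, `"reaction"`, `"go_bp"`, `"go_mf"`,
#'   `"go_cc"`, `"ec"`, `"ss"`, or `"custom"`.
#' @param level,out_dim,loss,max_len Overrides for a custom head.
#' @return A `task_head_spec`.
#' @export
task_head_spec <- function(task = c("fold", "reaction", "go_bp", "go_mf",
                                    "go_cc", "ec", "ss", "custom"),
                           level = NULL, out_dim = NULL, loss = NULL,
                           max_len = NULL) {
  task <- match.arg(task)
  preset <- switch(task,
    fold     = list(level = "protein", out_dim = 1195L, loss = "focal_multiclass", max_len = 512L),
    reaction = list(level = "protein", out_dim = 384L,  loss = "focal_multiclass", max_len = 512L),
    go_bp    = list(level = "protein", out_dim = 1943L, loss = "bce_multilabel",   max_len = 512L),
    go_mf    = list(level = "protein", out_dim = 489L,  loss = "bce_multilabel",   max_len = 512L),
    go_cc    = list(level = "protein", out_dim = 320L,  loss = "bce_multilabel",   max_len = 512L),
    ec       = list(level = "protein", out_dim = 538L,  loss = "bce_multilabel",   max_len = 512L),
    ss       = list(level = "residue", out_dim = 3L,    loss = "focal_multiclass", max_len = 1022L),
    custom   = list(level = "protein", out_dim = 2L,    loss = "focal_multiclass", max_len = 512L))
  out <- list(task = task,
              level = level %||% preset$level,
              out_dim = as.integer(out_dim %||% preset$out_dim),
              loss = loss %||% preset$loss,
              max_len = as.integer(max_len %||% preset$max_len))
  stopifnot(out$level %in% c("protein", "residue"),
            out$loss %in% c("focal_multiclass", "bce_multilabel"))
  structure(out, class = "task_head_spec")
}

#' Focal loss for multiclass classification
#'
#' `-(1 - p_t)^gamma * log(p_t)` for the target-class probability `p_t`,
#' averaged over the batch. `gamma = 0` reduces to cross-entropy.
#' Probabilities are clamped at `eps` to keep the log finite.
#'
#' @param probs `n x C` matrix of class probabilities (rows on the simplex),
#'   or a single probability vector.
#' @param target Integer class indices (length `n`).
#' @param gamma Focusing parameter (>= 0); default 2.
#' @param eps Clamping floor for `p_t`.
#' @return Scalar batch-averaged loss.
#' @export
focal_loss <- function(probs, target, gamma = 2, eps = 1e-12) {
  stopifnot(gamma >= 0)
  probs <- if (is.null(dim(probs))) matrix(probs, 1) else as.matrix(probs)
  stopifnot(nrow(probs) == length(target),
            all(target >= 1), all(target <= ncol(probs)))
  pt <- pmax(probs[cbind(seq_len(nrow(probs)), target)], eps)
  mean(-(1 - pt)^gamma * log(pt))
}

#' Multilabel binary cross-entropy (on logits)
#'
#' Mean over all (protein, label) entries of the logistic cross-entropy,
#' computed in a numerically stable form from logits.
#'
#' @param logits Numeric matrix (or vector) of scores.
#' @param targets Binary matrix of the same shape.
#' @return Scalar mean loss.
#' @export
multilabel_bce <- function(logits, targets) {
  logits <- as.matrix(logits); targets <- as.matrix(targets)
  stopifnot(all(dim(logits) == dim(targets)), all(targets %in% c(0, 1)))
  mean(pmax(logits, 0) - logits * targets + log1p(exp(-abs(logits))))
}

#' Protein-centric Fmax (CAFA convention)
#'
#' For each threshold `t` in the grid, a label is predicted when its score
#' is `>= t` and positive (a zero score means "not predicted"). Precision at
#' `t` is averaged over proteins with at least one predicted label; recall
#' is averaged over all proteins. Fmax is the maximum F1 of these averages
#' over the grid (thresholds where no protein predicts anything are skipped;
#' if that is every threshold, Fmax is 0).
#'
#' @param scores `proteins x labels` score matrix in `[0, 1]`.
#' @param truth Binary matrix of the same shape; every protein must have at
#'   least one positive label.
#' @param thresholds Threshold grid; default `seq(0, 1, by = 0.01)`.
#' @return Scalar in `[0, 1]`.
#' @export
fmax <- function(scores, truth, thresholds = seq(0, 1, by = 0.01)) {
  scores <- as.matrix(scores); truth <- as.matrix(truth)
  stopifnot(all(dim(scores) == dim(truth)), all(truth %in% c(0, 1)),
            all(thresholds >= 0), all(thresholds <= 1))
  if (any(rowSums(truth) == 0))
    stop("fmax: every protein needs at least one positive truth label")
  best <- 0
  for (t in thresholds) {
    pred <- (scores >= t) & (scores > 0)
    npred <- rowSums(pred)
    tp <- rowSums(pred & (truth == 1))
    has <- npred > 0
    if (!any(has)) next
    pr <- mean(tp[has] / npred[has])
    rc <- mean(tp / rowSums(truth))
    if (pr + rc > 0) best <- max(best, 2 * pr * rc / (pr + rc))
  }
  best
}

#' Residue-level accuracy (%)
#'
#' Fraction of correct predictions over mask-true residues, times 100.
#'
#' @param pred,true Integer label vectors (same length).
#' @param mask Logical vector marking valid (non-padding) residues.
#' @return Percentage in `[0, 100]`.
#' @export
residue_accuracy <- function(pred, true, mask = rep(TRUE, length(true))) {
  stopifnot(length(pred) == length(true), length(mask) == length(true))
  if (!any(mask)) stop("residue_accuracy: empty mask")
  100 * mean(pred[mask] == true[mask])
}

softmax_rows_stable <- function(Z) {
  m <- apply(Z, 1, max)
  E <- exp(Z - m)
  E / rowSums(E)
}

# gradient of batch-mean focal loss wrt logits
focal_grad_logits <- function(P, target, gamma, eps = 1e-12) {
  n <- nrow(P)
  pt <- pmax(P[cbind(seq_len(n), target)], eps)
  # dL/dp_t for L = -(1-p_t)^g log p_t
  dLdpt <- gamma * (1 - pt)^(pmax(gamma - 1, 0)) * log(pt) - (1 - pt)^gamma / pt
  if (gamma == 0) dLdpt <- -1 / pt
  G <- P * 0
  # dp_t/dz_j = p_t (1[j==t] - p_j)
  for (i in seq_len(n)) {
    G[i, ] <- dLdpt[i] * pt[i] * (-P[i, ])
    G[i, target[i]] <- G[i, target[i]] + dLdpt[i] * pt[i]
  }
  G / n
}

#' Train a dense classification head
#'
#' Fits the single dense layer (`d -> out_dim`, bias) used by every task
#' head, by full-batch gradient descent on the task loss, on fixed
#' embeddings ("fix" / frozen-encoder setting). Multiclass heads use softmax
#' + focal loss; multilabel heads use sigmoid + BCE.
#'
#' @param x Embedding matrix: one row per protein (protein-level) or per
#'   residue (residue-level).
#' @param labels Integer class vector (multiclass) or binary matrix
#'   (multilabel).
#' @param spec A [task_head_spec()].
#' @param epochs,lr Gradient-descent schedule.
#' @param gamma Focal focusing parameter.
#' @param seed Initialization seed.
#' @return A `task_head`: list with `W`, `b`, `spec`, and `history` (loss
#'   per epoch).
#' @export
train_head <- function(x, labels, spec, epochs = 200L, lr = 0.5, gamma = 2,
                       seed = 1L) {
  x <- as.matrix(x)
  stopifnot(inherits(spec, "task_head_spec"))
  C <- spec$out_dim
  multilabel <- spec$loss == "bce_multilabel"
  if (multilabel) {
    labels <- as.matrix(labels)
    stopifnot(nrow(labels) == nrow(x), ncol(labels) == C)
  } else {
    labels <- as.integer(labels)
    stopifnot(length(labels) == nrow(x), all(labels >= 1), all(labels <= C))
  }
  d <- ncol(x)
  W <- with_seed(seed, rmat(d, C, sd = 1 / sqrt(d)))
  b <- numeric(C)
  history <- numeric(epochs)
  for (e in seq_len(epochs)) {
    Z <- lin_fwd(x, W, b)
    if (multilabel) {
      P <- 1 / (1 + exp(-Z))
      history[e] <- multilabel_bce(Z, labels)
      G <- (P - labels) / length(Z)
    } else {
      P <- softmax_rows_stable(Z)
      history[e] <- focal_loss(P, labels, gamma = gamma)
      G <- focal_grad_logits(P, labels, gamma)
    }
    W <- W - lr * crossprod(x, G)
    b <- b - lr * colSums(G)
  }
  structure(list(W = W, b = b, spec = spec, history = history),
            class = "task_head")
}

#' Predict with a trained task head
#'
#' @param head A `task_head` from [train_head()].
#' @param x Embedding matrix.
#' @return Multiclass: list with `probs` and `class`; multilabel: list with
#'   `scores` (sigmoid probabilities).
#' @export
predict_head <- function(head, x) {
  Z <- lin_fwd(as.matrix(x), head$W, head$b)
  if (head$spec$loss == "bce_multilabel") {
    list(scores = 1 / (1 + exp(-Z)))
  } else {
    P <- softmax_rows_stable(Z)
    list(probs = P, class = max.col(P, ties.method = "first"))
  }
}

#' Fine-tune an encoder with a task head
#'
#' End-to-end training of a classification head on top of the sequence
#' encoder, under any adaptation strategy: `strategy = NULL` keeps the
#' encoder frozen ("fix"); otherwise an [adaptation_spec()] decides which
#' encoder parameters train alongside the (always trainable) head.
#' Protein-level tasks pool residue embeddings by masked mean; gradients
#' reach the encoder through the pooled embedding.
#'
#' @param model A sequence `encoder`.
#' @param records List of [protein_record()].
#' @param labels Integer class labels, one per record (multiclass heads).
#' @param spec A [task_head_spec()] with `level = "protein"`.
#' @param strategy Optional [adaptation_spec()].
#' @param epochs,lr Training schedule. @param gamma Focal parameter.
#' @param seed Initialization seed.
#' @return List with the adapted `model`, the `head`, and per-epoch `history`.
#' @export
finetune_encoder <- function(model, records, labels, spec, strategy = NULL,
                             epochs = 5L, lr = 0.1, gamma = 2, seed = 1L) {
  stopifnot(inherits(model, "encoder"), model$config$kind == "sequence",
            inherits(spec, "task_head_spec"), spec$level == "protein")
  labels <- as.integer(labels)
  if (any(labels < 1L) | any(labels > spec$out_dim))
    stop("finetune_encoder: label outside 1..out_dim")
  if (!is.null(strategy)) model <- apply_strategy(model, strategy, seed = seed)
  else model$trainable[] <- FALSE
  toks <- lapply(records, tokenize, max_len = spec$max_len)
  d <- model$config$embed_dim; C <- spec$out_dim
  W <- with_seed(seed, rmat(d, C, sd = 1 / sqrt(d)))
  b <- numeric(C)
  opt <- make_sgd()
  cfg <- pretrain_config(batch_size = 2L)   # reuse clip/momentum defaults
  history <- numeric(epochs)
  zero_proj <- numeric(model$config$proj_dim)
  for (e in seq_len(epochs)) {
    X <- matrix(0, length(records), d)
    caches <- vector("list", length(records))
    for (j in seq_along(records)) {
      sf <- seq_forward(model, toks[[j]], want_cache = TRUE)
      caches[[j]] <- sf$cache
      X[j, ] <- sf$bundle$protein_embedding
    }
    Z <- lin_fwd(X, W, b)
    P <- softmax_rows_stable(Z)
    history[e] <- focal_loss(P, labels, gamma = gamma)
    G <- focal_grad_logits(P, labels, gamma)
    dX <- G %*% t(W)
    if (any(model$trainable)) {
      gr <- new.env(parent = emptyenv())
      for (j in seq_along(records))
        seq_backward(model, caches[[j]], zero_proj, gr,
                     d_pooled_extra = dX[j, ])
      model <- sgd_step(model, gr, opt, lr, cfg)
    }
    W <- W - lr * crossprod(X, G)
    b <- b - lr * colSums(G)
  }
  head <- structure(list(W = W, b = b, spec = spec, history = history),
                    class = "task_head")
  list(model = model, head = head, history = history)
}
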
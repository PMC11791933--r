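# Lightweight-tuning toolbox: top-K fine-tuning, LoRA on the attention
# projections, serial bottleneck adapters (the Structure-Aware Module) and
# parallel task adapters, plus exact trainable-parameter accounting.

#' Adaptation specification
#'
#' Describes one lightweight-tuning strategy for the sequence encoder.
#'
#' @param strategy `"finetune_topK"`, `"lora"` or `"adapter"`.
#' @param K Number of top transformer layers affected.
#' @param r LoRA rank (low-rank update `delta_W = B A` of rank `r`).
#' @param alpha LoRA scaling constant; the update is scaled by `alpha / r`.
#' @param bottleneck Adapter hidden width `m`; default `embed_dim / 2`,
#'   resolved when the strategy is applied.
#' @param targets Attention projections carrying LoRA, subset of
#'   `c("query", "key", "value", "output")`.
#' @param n_parallel Number of parallel adapters per insertion point
#'   (the merge is `h + sum_i a_i(h)`).
#' @param trainable_adapter Index of the single trainable adapter in the
#'   parallel set (all others are frozen); default the last one.
#' @return An `adaptation_spec`.
#' @export
adaptation_spec <- function(strategy = c("finetune_topK", "lora", "adapter"),
                            K = 1L, r = 2L, alpha = 8,
                            bottleneck = NULL,
                            targets = c("query", "key", "value", "output"),
                            n_parallel = 1L, trainable_adapter = n_parallel) {
  strategy <- match.arg(strategy)
  stopifnot(K >= 1L, r >= 1L, n_parallel >= 1L)
  if (strategy == "lora") {
    if (length(targets) == 0L)
      stop("adaptation_spec: lora needs a non-empty targets set")
    targets <- match.arg(targets,
                         c("query", "key", "value", "output"),
                         several.ok = TRUE)
  }
  if (!is.null(bottleneck) && bottleneck < 1L)
    stop("adaptation_spec: bottleneck must be >= 1")
  structure(list(strategy = strategy, K = as.integer(K), r = as.integer(r),
                 alpha = alpha, bottleneck = bottleneck, targets = targets,
                 n_parallel = as.integer(n_parallel),
                 trainable_adapter = as.integer(trainable_adapter)),
            class = "adaptation_spec")
}

#' LoRA forward pass
#'
#' Computes `h = W0 x + (alpha / r) * B A x` for a frozen base matrix `W0`
#' and the trainable rank-`r` decomposition `delta_W = B A`. With
#' `alpha = r` this reduces to the unscaled form `(W0 + B A) x`.
#'
#' @param x Input vector of length `k` (column convention).
#' @param W0 Frozen `d x k` base matrix.
#' @param A `r x k` matrix. @param B `d x r` matrix.
#' @param alpha Scaling constant. @param r Rank.
#' @return Numeric vector of length `d`.
#' @export
lora_forward <- function(x, W0, A, B, alpha, r) {
  W0 <- as.matrix(W0); A <- as.matrix(A); B <- as.matrix(B)
  d <- nrow(W0); k <- ncol(W0)
  r_eff <- nrow(A)   # decomposition size; `r` itself only enters the scaling
  if (r_eff > min(d, k))
    stop("lora_forward: decomposition rank ", r_eff,
         " exceeds min(d, k) = ", min(d, k))
  stopifnot(ncol(A) == k, nrow(B) == d, ncol(B) == r_eff, length(x) == k)
  drop(W0 %*% x + (alpha / r) * (B %*% (A %*% x)))
}

#' Bottleneck adapter increment
#'
#' Computes the adapter increment
#' `a(h) = W_up %*% relu(W_down %*% h + b_down) + b_up`. The skip connection
#' is applied by the caller (see [merge_parallel()]).
#'
#' @param h Input vector of length `d`.
#' @param W_down `m x d` down-projection. @param b_down Length-`m` bias.
#' @param W_up `d x m` up-projection. @param b_up Length-`d` bias.
#' @return Numeric vector of length `d`.
#' @export
adapter_forward <- function(h, W_down, b_down, W_up, b_up) {
  W_down <- as.matrix(W_down); W_up <- as.matrix(W_up)
  stopifnot(ncol(W_down) == length(h), nrow(W_down) == length(b_down),
            ncol(W_up) == nrow(W_down), nrow(W_up) == length(b_up))
  drop(W_up %*% pmax(drop(W_down %*% h) + b_down, 0) + b_up)
}

#' Merge parallel adapters with a shared skip connection
#'
#' Computes `h' = h + sum_i a_i(h)` over `N >= 1` parallel adapters. At most
#' one adapter in the set may be flagged trainable (the new-task adapter);
#' the rest are frozen.
#'
#' @param h Input vector.
#' @param adapters List of adapter parameter sets, each a list with
#'   `W_down`, `b_down`, `W_up`, `b_up` and optionally `trainable` (logical).
#' @return Numeric vector, same length as `h`.
#' @export
merge_parallel <- function(h, adapters) {
  stopifnot(length(adapters) >= 1L)
  dims <- vapply(adapters, function(a) ncol(as.matrix(a$W_down)), 1L)
  if (any(dims != length(h)))
    stop("merge_parallel: adapter input dimension mismatch")
  n_train <- sum(vapply(adapters, function(a) isTRUE(a$trainable), TRUE))
  if (n_train > 1L)
    stop("merge_parallel: at most one adapter may be trainable")
  out <- h
  for (a in adapters)
    out <- out + adapter_forward(h, a$W_down, a$b_down, a$W_up, a$b_up)
  out
}

# parameter names belonging to layer i's base block
.layer_param_names <- function(i) {
  pre <- paste0("l", i, ".")
  c(paste0(pre, c("ln1.g", "ln1.b", "ln2.g", "ln2.b")),
    paste0(pre, "attn.", c("Wq", "bq", "Wk", "bk", "Wv", "bv", "Wo", "bo")),
    paste0(pre, "ffn.", c("W1", "b1", "W2", "b2")))
}

#' Apply a lightweight-tuning strategy to an encoder
#'
#' Freezes/unfreezes parameters and, for LoRA and adapter strategies, attaches
#' freshly initialized injected modules to the top-`K` layers:
#' * `finetune_topK`: the top `K` layers are trainable, everything else
#'   frozen. When `K` equals the layer count, the token embedding, final
#'   layer norm and projector are unfrozen too (full fine-tune limit).
#' * `lora`: rank-`r` pairs `A` (Gaussian) / `B` (zero) on the targeted
#'   attention projections; only these are trainable. Training therefore
#'   starts exactly at the base model.
#' * `adapter`: `n_parallel` bottleneck adapters at both insertion points
#'   (post-attention and post-feed-forward) of each top-`K` layer, `W_up`
#'   and biases zero-initialized (identity start); only the designated
#'   trainable adapter's parameters are trainable.
#'
#' @param model An `encoder`.
#' @param spec An [adaptation_spec()].
#' @param seed Seed for the injected-module initialization.
#' @return The modified `encoder`.
#' @export
apply_strategy <- function(model, spec, seed = 1L) {
  stopifnot(inherits(model, "encoder"), inherits(spec, "adaptation_spec"))
  cfg <- model$config
  if (spec$K > cfg$n_layers)
    stop("apply_strategy: K = ", spec$K, " exceeds n_layers = ", cfg$n_layers)
  d <- cfg$embed_dim
  model$trainable[] <- FALSE
  top <- .top_layers(cfg$n_layers, spec$K)
  if (spec$strategy == "finetune_topK") {
    for (i in top) model$trainable[.layer_param_names(i)] <- TRUE
    if (spec$K == cfg$n_layers) model$trainable[] <- TRUE
  } else if (spec$strategy == "lora") {
    if (spec$r > d)
      stop("apply_strategy: LoRA rank r = ", spec$r,
           " exceeds projection dimension ", d)
    with_seed(seed, {
      for (i in top) for (tgt in spec$targets) {
        nA <- paste0("l", i, ".lora.", tgt, ".A")
        nB <- paste0("l", i, ".lora.", tgt, ".B")
        model$params[[nA]] <- rmat(d, spec$r, sd = 1 / sqrt(d))
        model$params[[nB]] <- matrix(0, spec$r, d)
        model$trainable[nA] <- TRUE
        model$trainable[nB] <- TRUE
      }
    })
    model$lora <- list(K = spec$K, r = spec$r, alpha = spec$alpha,
                       targets = spec$targets)
  } else { # adapter
    m <- spec$bottleneck %||% max(1L, d %/% 2L)
    with_seed(seed, {
      for (i in top) for (where in c("ad1", "ad2"))
        for (j in seq_len(spec$n_parallel)) {
          ap <- paste0("l", i, ".", where, ".a", j, ".")
          model$params[[paste0(ap, "Wd")]] <- rmat(d, m, sd = 1 / sqrt(d))
          model$params[[paste0(ap, "bd")]] <- numeric(m)
          model$params[[paste0(ap, "Wu")]] <- matrix(0, m, d)
          model$params[[paste0(ap, "bu")]] <- numeric(d)
          tr <- j == spec$trainable_adapter
          model$trainable[paste0(ap, c("Wd", "bd", "Wu", "bu"))] <- tr
        }
    })
    model$adapters <- list(K = spec$K, bottleneck = m,
                           n_parallel = spec$n_parallel,
                           trainable_adapter = spec$trainable_adapter)
  }
  model
}

#' Set trainable flags by name pattern
#'
#' Marks every parameter whose name matches `pattern` as trainable (or
#' frozen). Typical use: unfreezing the projector for contrastive
#' pretraining after [apply_strategy()] froze the base encoder.
#'
#' @param model An `encoder`.
#' @param pattern Regular expression over parameter names.
#' @param value Logical flag to assign.
#' @return The modified `encoder`.
#' @export
set_trainable <- function(model, pattern, value = TRUE) {
  stopifnot(inherits(model, "encoder"))
  hit <- grepl(pattern, names(model$trainable))
  if (!any(hit)) stop("set_trainable: no parameter matches ", pattern)
  model$trainable[hit] <- value
  model
}

.component_of <- function(name) {
  if (name %in% c("tok_emb", "pos_emb", "patch_emb.W", "patch_emb.b"))
    return("embedding")
  if (grepl("^final_ln\\.", name)) return("final_layer_norm")
  if (grepl("^proj\\.", name)) return("projector")
  if (grepl("\\.lora\\.", name)) return("lora")
  if (grepl("\\.ad[12]\\.", name)) return("adapters")
  "transformer_layers"
}

#' Count trainable parameters of an adapted model
#'
#' Exact integer counts over the parameters currently flagged trainable,
#' broken down by component; optionally includes a dense classification head
#' (`embed_dim -> head_out`, with bias), which is always trainable.
#'
#' @param model An `encoder` after [apply_strategy()].
#' @param head_out Optional output dimension of a classification head.
#' @return A `param_report`: list with `per_component` (named integer
#'   vector of trainable counts), `trainable`, `frozen` and `total`.
#' @export
count_trainable <- function(model, head_out = NULL) {
  stopifnot(inherits(model, "encoder"))
  sizes <- vapply(model$params, length, 1L)
  comp <- vapply(names(sizes), .component_of, "")
  tr <- model$trainable[names(sizes)]
  per <- tapply(sizes * tr, comp, sum)
  per <- per[per > 0]
  per <- stats::setNames(as.integer(per), names(per))
  trainable <- sum(sizes[tr])
  total <- sum(sizes)
  if (!is.null(head_out)) {
    hd <- model$config$embed_dim * head_out + head_out
    per <- c(per, head = as.integer(hd))
    trainable <- trainable + hd
    total <- total + hd
  }
  structure(list(per_component = per, trainable = trainable,
                 frozen = total - trainable, total = total),
            class = "param_report")
}

#' @export
print.param_report <- function(x, ...) {
  cat("<param_report>\n")
  for (nm in names(x$per_component))
    cat(sprintf("  %-18s %12s\n", nm,
                format(x$per_component[[nm]], big.mark = ",")))
  cat(sprintf("  %-18s %12s\n", "trainable", format(x$trainable, big.mark = ",")))
  cat(sprintf("  %-18s %12s\n", "frozen", format(x$frozen, big.mark = ",")))
  invisible(x)
}

#' Closed-form trainable-parameter count for an encoder profile
#'
#' Computes, from shapes alone, the trainable-parameter count that
#' [count_trainable()] would report after [apply_strategy()] -- usable for
#' the full-size "full" profile without allocating its weights. Convention:
#' biases and layer-norm vectors are counted; LoRA matrices carry no biases.
#'
#' @param config An [encoder_config()].
#' @param spec An [adaptation_spec()].
#' @param head_out Optional classification-head output dimension.
#' @return Integer (exact count).
#' @export
count_trainable_profile <- function(config, spec, head_out = NULL) {
  stopifnot(inherits(config, "encoder_config"),
            inherits(spec, "adaptation_spec"))
  d <- config$embed_dim; f <- config$ffn_dim
  per_layer <- 4 * (d^2 + d) + (d * f + f) + (f * d + d) + 2 * 2 * d
  n <- switch(spec$strategy,
    finetune_topK = {
      base <- spec$K * per_layer
      if (spec$K == config$n_layers) {
        emb <- if (config$kind == "sequence")
          length(.VOCAB) * d + (config$max_len + 2) * d
        else
          (3 * config$patch_size^2) * d + d +
            (config$input_side %/% config$patch_size)^2 * d
        pd <- config$proj_dim
        base <- base + emb + 2 * d + (d * pd + pd) + (pd * pd + pd)
      }
      base
    },
    lora = spec$K * length(spec$targets) * 2 * d * spec$r,
    adapter = {
      m <- spec$bottleneck %||% max(1L, d %/% 2L)
      spec$K * 2 * (d * m + m + m * d + d)
    })
  if (!is.null(head_out)) n <- n + d * head_out + head_out
  as.integer(round(n))
}
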
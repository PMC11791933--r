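# Contrastive pretraining loop: two SGD-with-momentum optimizers (one per
# encoder backbone), sawtooth cyclic learning rate, global gradient-norm
# clipping, drop-last batching, per-step TSV metrics log.

#' Pretraining configuration
#'
#' Defaults follow the reference training recipe: batch size 20, temperature
#' 0.05, cyclic learning rate decaying linearly from 0.001 to 0 over 100
#' steps per cycle (instant restart), SGD momentum 0.9, weight decay 0.0005,
#' gradient-norm clipping at 1.0, 512-residue truncation.
#'
#' @param batch_size Proteins per step (`N`; at least 2).
#' @param tau Contrastive temperature.
#' @param lr_max Peak learning rate.
#' @param cycle_steps Steps per learning-rate cycle.
#' @param momentum SGD momentum.
#' @param weight_decay L2 weight decay on trainable parameters.
#' @param grad_clip_norm Global gradient-norm clip threshold.
#' @param max_len Residue truncation for both modalities.
#' @param epochs Passes over the corpus.
#' @param seed Seed for the per-epoch shuffling.
#' @param mixed_precision Accepted for interface compatibility; this CPU
#'   implementation always computes in double precision, so the flag must be
#'   `FALSE` (determinism).
#' @param include_positive_in_denominator,symmetrize Loss variant flags, see
#'   [multiview_loss()].
#' @return A `pretrain_config`.
#' @export
pretrain_config <- function(batch_size = 20L, tau = 0.05, lr_max = 0.001,
                            cycle_steps = 100L, momentum = 0.9,
                            weight_decay = 5e-4, grad_clip_norm = 1.0,
                            max_len = 512L, epochs = 5L, seed = 1L,
                            mixed_precision = FALSE,
                            include_positive_in_denominator = FALSE,
                            symmetrize = FALSE) {
  stopifnot(batch_size >= 2L, tau > 0, lr_max >= 0, cycle_steps >= 1L,
            epochs >= 1L)
  if (isTRUE(mixed_precision))
    stop("pretrain_config: mixed precision is not available in this ",
         "double-precision implementation")
  structure(list(batch_size = as.integer(batch_size), tau = tau,
                 lr_max = lr_max, cycle_steps = as.integer(cycle_steps),
                 momentum = momentum, weight_decay = weight_decay,
                 grad_clip_norm = grad_clip_norm, max_len = as.integer(max_len),
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 mixed_precision = FALSE,
                 include_positive_in_denominator =
                   include_positive_in_denominator,
                 symmetrize = symmetrize),
            class = "pretrain_config")
}

#' Cyclic (sawtooth) learning rate
#'
#' `lr = lr_max * (1 - (step %% cycle_steps) / cycle_steps)`: linear decay
#' from `lr_max` towards 0 over one cycle, restarting instantly.
#'
#' @param step Zero-based global step.
#' @param cfg A [pretrain_config()].
#' @return Learning rate at `step`.
#' @export
lr_at <- function(step, cfg) {
  stopifnot(step >= 0)
  cfg$lr_max * (1 - (step %% cfg$cycle_steps) / cfg$cycle_steps)
}

make_sgd <- function() new.env(parent = emptyenv())

# clip-by-global-norm then SGD-with-momentum + L2 weight decay
sgd_step <- function(model, gr, opt, lr, cfg) {
  names_tr <- names(model$trainable)[model$trainable]
  sq <- 0
  for (nm in names_tr) {
    g <- gr[[nm]]
    if (!is.null(g)) sq <- sq + sum(g * g)
  }
  gnorm <- sqrt(sq)
  scale <- if (gnorm > cfg$grad_clip_norm) cfg$grad_clip_norm / gnorm else 1
  for (nm in names_tr) {
    g <- gr[[nm]]
    if (is.null(g)) next
    g <- g * scale + cfg$weight_decay * model$params[[nm]]
    v <- opt[[nm]]
    v <- if (is.null(v)) g else cfg$momentum * v + g
    opt[[nm]] <- v
    model$params[[nm]] <- model$params[[nm]] - lr * v
  }
  model
}

# first layer index with any trainable parameter (1 when the embedding
# tables themselves train); layers below it never change during training,
# so their activations can be computed once per protein
frozen_prefix_depth <- function(model) {
  tr <- model$trainable
  emb_names <- grep("^(tok_emb|pos_emb|patch_emb)", names(tr), value = TRUE)
  if (any(tr[emb_names])) return(1L)
  for (i in seq_len(model$config$n_layers)) {
    if (any(tr[grepl(paste0("^l", i, "\\."), names(tr))])) return(i)
  }
  model$config$n_layers + 1L
}

prepare_struct_inputs <- function(records, str_model, max_len, d = 22) {
  lapply(records, function(r) {
    if (is.null(r$coords))
      stop("pretrain: record ", r$id, " has no coordinates")
    resize_for_encoder(featurize(distance_matrix(r$coords), d = d,
                                 max_len = max_len),
                       side = str_model$config$input_side,
                       patch_size = str_model$config$patch_size)
  })
}

#' Contrastive pretraining of the twin encoders
#'
#' Trains the sequence and structure encoders (each with its own SGD
#' optimizer, per the two-backbone recipe) to minimize the multi-view
#' contrastive loss over a corpus of paired sequence/structure records.
#' Deterministic given `cfg$seed`. Incomplete trailing batches are dropped
#' (the loss needs `N >= 2`).
#'
#' @param records List of [protein_record()], all with coordinates.
#' @param seq_model,str_model Initialized encoders (optionally already
#'   carrying an [apply_strategy()] adaptation, e.g. frozen base plus
#'   Structure-Aware adapters).
#' @param cfg A [pretrain_config()].
#' @param log_file Optional path for a TSV metrics log (step, lr, loss).
#' @param verbose Print per-epoch mean loss.
#' @return A `pretrain_result`: list with the trained `seq_model`,
#'   `str_model`, a `metrics` data frame, and `cfg`.
#' @export
pretrain <- function(records, seq_model, str_model, cfg = pretrain_config(),
                     log_file = NULL, verbose = FALSE) {
  stopifnot(inherits(seq_model, "encoder"), seq_model$config$kind == "sequence",
            inherits(str_model, "encoder"), str_model$config$kind == "structure")
  toks <- lapply(records, tokenize, max_len = cfg$max_len)
  sinputs <- prepare_struct_inputs(records, str_model, cfg$max_len)
  n <- length(records)
  # cache activations under the frozen prefix of the sequence encoder once
  j0 <- frozen_prefix_depth(seq_model)
  seq_prefixes <- NULL
  if (j0 > 1L) {
    seq_prefixes <- lapply(toks, function(ts) {
      X <- seq_model$params$tok_emb[ts$token_ids, , drop = FALSE] +
        seq_model$params$pos_emb[seq_along(ts$token_ids), , drop = FALSE]
      kmask <- ts$token_ids != .ID_PAD
      for (i in seq_len(j0 - 1L))
        X <- layer_fwd(X, i, seq_model, kmask, adapters_enabled = TRUE)$Y
      list(X = X, start_layer = j0)
    })
  }
  opt_seq <- make_sgd(); opt_str <- make_sgd()
  metrics <- list()
  step <- 0L
  for (epoch in seq_len(cfg$epochs)) {
    ord <- with_seed(cfg$seed + epoch, sample.int(n))
    n_batches <- n %/% cfg$batch_size
    for (b in seq_len(n_batches)) {
      idx <- ord[((b - 1L) * cfg$batch_size + 1L):(b * cfg$batch_size)]
      lr <- lr_at(step, cfg)
      N <- length(idx)
      pd <- seq_model$config$proj_dim
      S <- matrix(0, N, pd); C <- matrix(0, N, pd)
      scaches <- vector("list", N); ccaches <- vector("list", N)
      for (j in seq_len(N)) {
        sf <- seq_forward(seq_model, toks[[idx[j]]], want_cache = TRUE,
                          prefix = if (is.null(seq_prefixes)) NULL
                                   else seq_prefixes[[idx[j]]])
        S[j, ] <- sf$bundle$projected
        scaches[[j]] <- sf$cache
        st <- str_forward(str_model, sinputs[[idx[j]]], want_cache = TRUE)
        C[j, ] <- st$bundle$projected
        ccaches[[j]] <- st$cache
      }
      lg <- multiview_loss_grad(S, C, tau = cfg$tau,
                                include_positive_in_denominator =
                                  cfg$include_positive_in_denominator)
      d_seq <- lg$d_seq; d_str <- lg$d_str; loss <- lg$loss
      if (isTRUE(cfg$symmetrize)) {
        lg2 <- multiview_loss_grad(C, S, tau = cfg$tau,
                                   include_positive_in_denominator =
                                     cfg$include_positive_in_denominator)
        loss <- (loss + lg2$loss) / 2
        d_seq <- (d_seq + lg2$d_str) / 2
        d_str <- (d_str + lg2$d_seq) / 2
      }
      if (lr > 0) {
        gr_seq <- new.env(parent = emptyenv())
        gr_seq[[".tr"]] <- seq_model$trainable
        gr_str <- new.env(parent = emptyenv())
        gr_str[[".tr"]] <- str_model$trainable
        for (j in seq_len(N)) {
          seq_backward(seq_model, scaches[[j]], d_seq[j, ], gr_seq)
          str_backward(str_model, ccaches[[j]], d_str[j, ], gr_str)
          scaches[j] <- list(NULL); ccaches[j] <- list(NULL)
        }
        seq_model <- sgd_step(seq_model, gr_seq, opt_seq, lr, cfg)
        str_model <- sgd_step(str_model, gr_str, opt_str, lr, cfg)
      }
      metrics[[length(metrics) + 1L]] <-
        data.frame(step = step, epoch = epoch, lr = lr, loss = loss)
      step <- step + 1L
    }
    if (verbose) {
      ep <- do.call(rbind, metrics)
      message(sprintf("epoch %d: mean loss %.4f", epoch,
                      mean(ep$loss[ep$epoch == epoch])))
    }
  }
  metrics <- do.call(rbind, metrics)
  if (!is.null(log_file))
    utils::write.table(metrics, log_file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  structure(list(seq_model = seq_model, str_model = str_model,
                 metrics = metrics, cfg = cfg),
            class = "pretrain_result")
}

#' Embed a corpus with a trained encoder
#'
#' Sequence-only input is the primary inference mode: records are tokenized
#' and run through the sequence encoder. With a structure encoder, records
#' must carry coordinates and are featurized to contact maps first.
#'
#' @param model An `encoder`.
#' @param records List of [protein_record()].
#' @param level `"protein"` (pooled, `embed_dim` columns), `"projected"`
#'   (256 columns) or `"residue"` (one row per residue).
#' @param max_len Truncation limit.
#' @param adapters_enabled Passed through to the encoder.
#' @return A data frame: `id` (and `position` for residue level) plus one
#'   column per embedding dimension.
#' @export
embed_records <- function(model, records,
                          level = c("protein", "projected", "residue"),
                          max_len = 512L, adapters_enabled = TRUE) {
  level <- match.arg(level)
  stopifnot(inherits(model, "encoder"))
  if (model$config$kind == "structure" && level == "residue")
    stop("embed_records: residue level requires the sequence encoder")
  rows <- lapply(records, function(r) {
    bundle <- if (model$config$kind == "sequence") {
      seq_forward(model, tokenize(r, max_len = max_len),
                  adapters_enabled = adapters_enabled)
    } else {
      if (is.null(r$coords))
        stop("embed_records: record ", r$id, " has no coordinates but the ",
             "model encodes structures")
      si <- resize_for_encoder(featurize(distance_matrix(r$coords),
                                         max_len = max_len),
                               side = model$config$input_side,
                               patch_size = model$config$patch_size)
      str_forward(model, si)
    }
    switch(level,
      protein = data.frame(id = r$id, t(bundle$protein_embedding)),
      projected = data.frame(id = r$id, t(bundle$projected)),
      residue = data.frame(id = r$id,
                           position = seq_len(nrow(bundle$residue_embeddings)),
                           bundle$residue_embeddings))
  })
  out <- do.call(rbind, rows)
  emb_cols <- setdiff(names(out), c("id", "position"))
  names(out)[match(emb_cols, names(out))] <- paste0("e", seq_along(emb_cols))
  rownames(out) <- NULL
  out
}
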
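# Twin encoders: a token transformer for amino-acid sequences and a
# patch transformer for 3-channel contact maps, each with masked mean
# pooling and a 2-layer projector to a shared 256-d space.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Encoder configuration
#'
#' Builds the architecture description for one encoder. Two named profiles
#' exist: `"tiny"` (2 layers, width 32 -- sized so contrastive pretraining on
#' a synthetic corpus takes CPU minutes) and `"full"` (the 33-layer,
#' 1280-wide sequence transformer and a 256-resolution patch encoder; used
#' for trainable-parameter accounting only, never instantiated or trained
#' here). Any field can be overridden for a custom profile.
#'
#' @param profile `"tiny"`, `"full"` or `"custom"`.
#' @param kind `"sequence"` or `"structure"`.
#' @param n_layers,embed_dim,ffn_dim,n_heads Transformer shape; `embed_dim`
#'   must be divisible by `n_heads`.
#' @param max_len Residue truncation limit (sequence kind).
#' @param patch_size,input_side Patch geometry (structure kind);
#'   `input_side` must be divisible by `patch_size`.
#' @param proj_dim Projector output dimension (256 throughout).
#' @param activation Nonlinearity between the two projector layers and in the
#'   feed-forward blocks; `"relu"` only.
#' @return An `encoder_config` list.
#' @export
encoder_config <- function(profile = c("tiny", "full", "custom"),
                           kind = c("sequence", "structure"),
                           n_layers = NULL, embed_dim = NULL, ffn_dim = NULL,
                           n_heads = NULL, max_len = 512L,
                           patch_size = NULL, input_side = NULL,
                           proj_dim = 256L, activation = "relu") {
  profile <- match.arg(profile)
  kind <- match.arg(kind)
  def <- switch(profile,
    tiny  = list(n_layers = 2L, embed_dim = 32L, ffn_dim = 64L, n_heads = 4L,
                 patch_size = 8L, input_side = 32L),
    full = if (kind == "sequence")
      list(n_layers = 33L, embed_dim = 1280L, ffn_dim = 5120L, n_heads = 20L,
           patch_size = 4L, input_side = 256L)
    else
      list(n_layers = 12L, embed_dim = 96L, ffn_dim = 384L, n_heads = 4L,
           patch_size = 4L, input_side = 256L),
    custom = list(n_layers = 2L, embed_dim = 32L, ffn_dim = 64L, n_heads = 4L,
                  patch_size = 8L, input_side = 32L))
  cfg <- list(profile = profile, kind = kind,
              n_layers = as.integer(n_layers %||% def$n_layers),
              embed_dim = as.integer(embed_dim %||% def$embed_dim),
              ffn_dim = as.integer(ffn_dim %||% def$ffn_dim),
              n_heads = as.integer(n_heads %||% def$n_heads),
              max_len = as.integer(max_len),
              patch_size = as.integer(patch_size %||% def$patch_size),
              input_side = as.integer(input_side %||% def$input_side),
              proj_dim = as.integer(proj_dim), activation = activation)
  if (cfg$embed_dim %% cfg$n_heads != 0L)
    stop("encoder_config: embed_dim must be divisible by n_heads")
  if (kind == "structure" && cfg$input_side %% cfg$patch_size != 0L)
    stop("encoder_config: input_side must be divisible by patch_size")
  structure(cfg, class = "encoder_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

rmat <- function(nr, nc, sd) matrix(stats::rnorm(nr * nc, sd = sd), nr, nc)

#' Initialize an encoder
#'
#' Deterministically initializes all weights from `seed`: dense layers with
#' sd `1/sqrt(fan_in)`, zero biases, unit layer-norm gains.
#'
#' @param config An [encoder_config()].
#' @param seed Integer seed.
#' @return An `encoder` model object (config, flat named parameter list,
#'   trainable flags).
#' @export
init_encoder <- function(config, seed = 1L) {
  stopifnot(inherits(config, "encoder_config"))
  d <- config$embed_dim; f <- config$ffn_dim; pd <- config$proj_dim
  with_seed(seed, {
    p <- list()
    if (config$kind == "sequence") {
      p[["tok_emb"]] <- rmat(length(.VOCAB), d, sd = 1)
      # learned positions, initialized small so content dominates early
      p[["pos_emb"]] <- rmat(config$max_len + 2L, d, sd = 0.02)
    } else {
      pdim <- 3L * config$patch_size^2
      p[["patch_emb.W"]] <- rmat(pdim, d, sd = 1 / sqrt(pdim))
      p[["patch_emb.b"]] <- numeric(d)
      np <- (config$input_side %/% config$patch_size)^2
      p[["pos_emb"]] <- rmat(np, d, sd = 0.02)
    }
    for (i in seq_len(config$n_layers)) {
      pre <- paste0("l", i, ".")
      p[[paste0(pre, "ln1.g")]] <- rep(1, d)
      p[[paste0(pre, "ln1.b")]] <- numeric(d)
      for (w in c("Wq", "Wk", "Wv", "Wo"))
        p[[paste0(pre, "attn.", w)]] <- rmat(d, d, sd = 1 / sqrt(d))
      for (b in c("bq", "bk", "bv", "bo"))
        p[[paste0(pre, "attn.", b)]] <- numeric(d)
      p[[paste0(pre, "ln2.g")]] <- rep(1, d)
      p[[paste0(pre, "ln2.b")]] <- numeric(d)
      p[[paste0(pre, "ffn.W1")]] <- rmat(d, f, sd = 1 / sqrt(d))
      p[[paste0(pre, "ffn.b1")]] <- numeric(f)
      p[[paste0(pre, "ffn.W2")]] <- rmat(f, d, sd = 1 / sqrt(f))
      p[[paste0(pre, "ffn.b2")]] <- numeric(d)
    }
    p[["final_ln.g"]] <- rep(1, d)
    p[["final_ln.b"]] <- numeric(d)
    p[["proj.W1"]] <- rmat(d, pd, sd = 1 / sqrt(d))
    p[["proj.b1"]] <- numeric(pd)
    p[["proj.W2"]] <- rmat(pd, pd, sd = 1 / sqrt(pd))
    p[["proj.b2"]] <- numeric(pd)
    structure(list(config = config, params = p,
                   trainable = stats::setNames(rep(TRUE, length(p)), names(p)),
                   lora = NULL, adapters = NULL),
              class = "encoder")
  })
}

#' @export
print.encoder <- function(x, ...) {
  cat("<encoder> ", x$config$kind, " (", x$config$profile, "): ",
      x$config$n_layers, " layers, dim ", x$config$embed_dim,
      ", ", sum(vapply(x$params, length, 1L)), " parameters\n", sep = "")
  invisible(x)
}

# layer index range carrying injected modules
.top_layers <- function(n_layers, K) (n_layers - K + 1L):n_layers

# forward through one transformer block; returns list(Y, cache)
layer_fwd <- function(X, i, model, kmask, adapters_enabled) {
  p <- model$params
  pre <- paste0("l", i, ".")
  cfg <- model$config
  lora <- NULL
  if (!is.null(model$lora) && adapters_enabled &&
      i %in% .top_layers(cfg$n_layers, model$lora$K)) {
    lora <- list(scale = model$lora$alpha / model$lora$r)
    for (tgt in model$lora$targets)
      lora[[tgt]] <- list(A = p[[paste0(pre, "lora.", tgt, ".A")]],
                          B = p[[paste0(pre, "lora.", tgt, ".B")]])
  }
  has_ad <- !is.null(model$adapters) && adapters_enabled &&
    i %in% .top_layers(cfg$n_layers, model$adapters$K)
  run_adapters <- function(X, where) {
    if (!has_ad) return(list(Y = X, caches = NULL))
    caches <- vector("list", model$adapters$n_parallel)
    Y <- X
    for (j in seq_len(model$adapters$n_parallel)) {
      ap <- paste0(pre, where, ".a", j, ".")
      cj <- ad_fwd(X, p[[paste0(ap, "Wd")]], p[[paste0(ap, "bd")]],
                   p[[paste0(ap, "Wu")]], p[[paste0(ap, "bu")]])
      Y <- Y + cj$Y
      caches[[j]] <- cj
    }
    list(Y = Y, caches = caches)
  }
  ln1 <- ln_fwd(X, p[[paste0(pre, "ln1.g")]], p[[paste0(pre, "ln1.b")]])
  at <- attn_fwd(ln1$Y, list(Wq = p[[paste0(pre, "attn.Wq")]],
                             bq = p[[paste0(pre, "attn.bq")]],
                             Wk = p[[paste0(pre, "attn.Wk")]],
                             bk = p[[paste0(pre, "attn.bk")]],
                             Wv = p[[paste0(pre, "attn.Wv")]],
                             bv = p[[paste0(pre, "attn.bv")]],
                             Wo = p[[paste0(pre, "attn.Wo")]],
                             bo = p[[paste0(pre, "attn.bo")]]),
                 cfg$n_heads, kmask = kmask, lora = lora)
  r1 <- X + at$Y
  a1 <- run_adapters(r1, "ad1")
  ln2 <- ln_fwd(a1$Y, p[[paste0(pre, "ln2.g")]], p[[paste0(pre, "ln2.b")]])
  pre_f <- lin_fwd(ln2$Y, p[[paste0(pre, "ffn.W1")]], p[[paste0(pre, "ffn.b1")]])
  hid_f <- relu(pre_f)
  ffn <- lin_fwd(hid_f, p[[paste0(pre, "ffn.W2")]], p[[paste0(pre, "ffn.b2")]])
  r2 <- a1$Y + ffn
  a2 <- run_adapters(r2, "ad2")
  list(Y = a2$Y,
       cache = list(ln1 = ln1, at = at, a1 = a1, ln2 = ln2, pre_f = pre_f,
                    hid_f = hid_f, a2 = a2, lora = lora, has_ad = has_ad))
}

layer_bwd <- function(dY, i, model, cache, kmask, gr) {
  p <- model$params
  pre <- paste0("l", i, ".")
  cfg <- model$config
  bwd_adapters <- function(dOut, caches, where) {
    # y = x + sum_j a_j(x): route dOut through every adapter and the skip
    dX <- dOut
    for (j in seq_along(caches)) {
      ap <- paste0(pre, where, ".a", j, ".")
      dX <- dX + ad_bwd(dOut, caches[[j]], p[[paste0(ap, "Wd")]],
                        p[[paste0(ap, "Wu")]], gr, ap)
    }
    dX
  }
  d_r2 <- if (cache$has_ad) bwd_adapters(dY, cache$a2$caches, "ad2") else dY
  # r2 = a1out + ffn(ln2(a1out))
  dhid <- lin_bwd(d_r2, cache$hid_f, p[[paste0(pre, "ffn.W2")]], gr,
                  paste0(pre, "ffn.W2"), paste0(pre, "ffn.b2"))
  dpre <- dhid * (cache$pre_f > 0)
  dln2 <- lin_bwd(dpre, cache$ln2$Y, p[[paste0(pre, "ffn.W1")]], gr,
                  paste0(pre, "ffn.W1"), paste0(pre, "ffn.b1"))
  d_a1 <- d_r2 + ln_bwd(dln2, cache$ln2, p[[paste0(pre, "ln2.g")]], gr,
                        paste0(pre, "ln2.g"), paste0(pre, "ln2.b"))
  d_r1 <- if (cache$has_ad) bwd_adapters(d_a1, cache$a1$caches, "ad1") else d_a1
  # r1 = x + attn(ln1(x))
  dattn_in <- attn_bwd(d_r1, cache$at$cache,
                       list(Wq = p[[paste0(pre, "attn.Wq")]],
                            Wk = p[[paste0(pre, "attn.Wk")]],
                            Wv = p[[paste0(pre, "attn.Wv")]],
                            Wo = p[[paste0(pre, "attn.Wo")]]),
                       cfg$n_heads, gr, paste0(pre, "attn."),
                       lora = cache$lora, lora_prefix = paste0(pre, "lora."))
  d_r1 + ln_bwd(dattn_in, cache$ln1, p[[paste0(pre, "ln1.g")]], gr,
                paste0(pre, "ln1.g"), paste0(pre, "ln1.b"))
}

proj_fwd <- function(model, x) {
  p <- model$params
  pre1 <- drop(x %*% p[["proj.W1"]]) + p[["proj.b1"]]
  hid <- relu(pre1)
  y <- drop(hid %*% p[["proj.W2"]]) + p[["proj.b2"]]
  list(y = y, pre1 = pre1, hid = hid, x = x)
}

proj_bwd <- function(dY, cache, model, gr) {
  p <- model$params
  if (need_g(gr, "proj.W2")) addg(gr, "proj.W2", outer(cache$hid, dY))
  if (need_g(gr, "proj.b2")) addg(gr, "proj.b2", dY)
  dhid <- drop(p[["proj.W2"]] %*% dY)
  dpre <- dhid * (cache$pre1 > 0)
  if (need_g(gr, "proj.W1")) addg(gr, "proj.W1", outer(cache$x, dpre))
  if (need_g(gr, "proj.b1")) addg(gr, "proj.b1", dpre)
  drop(p[["proj.W1"]] %*% dpre)
}

#' Masked mean pooling
#'
#' Arithmetic mean of the rows marked `TRUE` in the validity mask; the
#' protein-level embedding is this mean over real residues (or valid
#' patches), excluding BEGIN/END/PAD positions.
#'
#' @param residue_embeddings Numeric matrix, one row per position.
#' @param mask Logical vector, `TRUE` for rows entering the mean.
#' @return Numeric vector (one value per embedding dimension).
#' @export
mean_pool <- function(residue_embeddings, mask) {
  stopifnot(nrow(residue_embeddings) == length(mask))
  if (!any(mask)) stop("mean_pool: empty mask")
  colMeans(residue_embeddings[mask, , drop = FALSE])
}

# full sequence-encoder forward; returns bundle (+ cache when requested).
# `prefix` optionally supplies precomputed activations entering layer
# `prefix$start_layer` (valid only while everything below is frozen).
seq_forward <- function(model, ts, adapters_enabled = TRUE,
                        want_cache = FALSE, prefix = NULL) {
  stopifnot(inherits(ts, "token_seq"))
  if (any(ts$token_ids < 1L | ts$token_ids > nrow(model$params$tok_emb)))
    stop("encode_sequence: token id out of vocabulary")
  d <- model$config$embed_dim
  n_tok <- length(ts$token_ids)
  if (n_tok > nrow(model$params$pos_emb))
    stop("encode_sequence: token sequence longer than the positional table; ",
         "tokenize with max_len <= ", nrow(model$params$pos_emb) - 2L)
  kmask <- ts$token_ids != .ID_PAD
  start_layer <- 1L
  if (is.null(prefix)) {
    X <- model$params$tok_emb[ts$token_ids, , drop = FALSE] +
      model$params$pos_emb[seq_len(n_tok), , drop = FALSE]
  } else {
    X <- prefix$X
    start_layer <- prefix$start_layer
  }
  caches <- if (want_cache) vector("list", model$config$n_layers)
  for (i in seq(from = start_layer, length.out =
                  model$config$n_layers - start_layer + 1L)) {
    lf <- layer_fwd(X, i, model, kmask, adapters_enabled)
    X <- lf$Y
    if (want_cache) caches[[i]] <- lf$cache
  }
  lnf <- ln_fwd(X, model$params[["final_ln.g"]], model$params[["final_ln.b"]])
  H <- lnf$Y
  pooled <- mean_pool(H, ts$mask)
  pj <- proj_fwd(model, pooled)
  bundle <- structure(list(residue_embeddings = H[ts$mask, , drop = FALSE],
                           protein_embedding = pooled, projected = pj$y,
                           modality = "sequence"),
                      class = "embedding_bundle")
  if (!want_cache) return(bundle)
  list(bundle = bundle,
       cache = list(ts = ts, kmask = kmask, layers = caches, lnf = lnf,
                    H = H, pj = pj, adapters_enabled = adapters_enabled,
                    start_layer = start_layer))
}

seq_backward <- function(model, cache, d_projected, gr,
                         d_pooled_extra = NULL) {
  d_pooled <- proj_bwd(d_projected, cache$pj, model, gr)
  if (!is.null(d_pooled_extra)) d_pooled <- d_pooled + d_pooled_extra
  ts <- cache$ts
  n_valid <- sum(ts$mask)
  dH <- matrix(0, length(ts$token_ids), model$config$embed_dim)
  dH[ts$mask, ] <- matrix(d_pooled / n_valid, n_valid,
                          model$config$embed_dim, byrow = TRUE)
  dX <- ln_bwd(dH, cache$lnf, model$params[["final_ln.g"]], gr,
               "final_ln.g", "final_ln.b")
  start_layer <- cache$start_layer %||% 1L
  for (i in rev(seq(from = start_layer, length.out =
                      model$config$n_layers - start_layer + 1L)))
    dX <- layer_bwd(dX, i, model, cache$layers[[i]], cache$kmask, gr)
  if (start_layer > 1L) return(invisible(NULL))  # everything below frozen
  # scatter into token-embedding and position rows
  if (need_g(gr, "tok_emb")) {
    dE <- matrix(0, nrow(model$params$tok_emb), model$config$embed_dim)
    agg <- rowsum(dX, ts$token_ids)
    dE[as.integer(rownames(agg)), ] <- agg
    addg(gr, "tok_emb", dE)
  }
  if (need_g(gr, "pos_emb")) {
    dP <- matrix(0, nrow(model$params$pos_emb), model$config$embed_dim)
    dP[seq_len(nrow(dX)), ] <- dX
    addg(gr, "pos_emb", dP)
  }
  invisible(NULL)
}

patchify <- function(si) {
  ps <- si$patch_size; P <- si$side %/% ps
  M <- matrix(0, P * P, 3L * ps * ps)
  k <- 0L
  for (pc in seq_len(P)) for (pr in seq_len(P)) {
    k <- k + 1L
    rows <- ((pr - 1L) * ps + 1L):(pr * ps)
    cols <- ((pc - 1L) * ps + 1L):(pc * ps)
    M[k, ] <- as.vector(si$values[, rows, cols])
  }
  M
}

str_forward <- function(model, si, want_cache = FALSE) {
  stopifnot(inherits(si, "struct_input"))
  if (si$side != model$config$input_side)
    stop("encode_structure: input side ", si$side,
         " does not match encoder input_side ", model$config$input_side)
  kmask <- as.vector(si$patch_mask)
  if (!any(kmask)) stop("encode_structure: all patches masked out")
  Mp <- patchify(si)
  X <- lin_fwd(Mp, model$params[["patch_emb.W"]], model$params[["patch_emb.b"]]) +
    model$params[["pos_emb"]]
  caches <- if (want_cache) vector("list", model$config$n_layers)
  for (i in seq_len(model$config$n_layers)) {
    lf <- layer_fwd(X, i, model, kmask, adapters_enabled = TRUE)
    X <- lf$Y
    if (want_cache) caches[[i]] <- lf$cache
  }
  lnf <- ln_fwd(X, model$params[["final_ln.g"]], model$params[["final_ln.b"]])
  H <- lnf$Y
  pooled <- mean_pool(H, kmask)
  pj <- proj_fwd(model, pooled)
  bundle <- structure(list(residue_embeddings = H[kmask, , drop = FALSE],
                           protein_embedding = pooled, projected = pj$y,
                           modality = "structure"),
                      class = "embedding_bundle")
  if (!want_cache) return(bundle)
  list(bundle = bundle,
       cache = list(Mp = Mp, kmask = kmask, layers = caches, lnf = lnf,
                    H = H, pj = pj))
}

str_backward <- function(model, cache, d_projected, gr) {
  d_pooled <- proj_bwd(d_projected, cache$pj, model, gr)
  kmask <- cache$kmask
  n_valid <- sum(kmask)
  dH <- matrix(0, length(kmask), model$config$embed_dim)
  dH[kmask, ] <- matrix(d_pooled / n_valid, n_valid,
                        model$config$embed_dim, byrow = TRUE)
  dX <- ln_bwd(dH, cache$lnf, model$params[["final_ln.g"]], gr,
               "final_ln.g", "final_ln.b")
  for (i in rev(seq_len(model$config$n_layers)))
    dX <- layer_bwd(dX, i, model, cache$layers[[i]], kmask, gr)
  addg(gr, "pos_emb", dX)
  lin_bwd(dX, cache$Mp, model$params[["patch_emb.W"]], gr,
          "patch_emb.W", "patch_emb.b")
  invisible(NULL)
}

#' Encode a protein sequence
#'
#' Runs the sequence transformer over a tokenized protein and returns the
#' per-residue embeddings (special tokens excluded), the masked mean-pooled
#' protein-level embedding, and the 256-d projected embedding.
#'
#' @param model A sequence `encoder`.
#' @param tokens A `token_seq` from [tokenize()].
#' @param adapters_enabled When `FALSE`, all injected modules (bottleneck
#'   adapters and LoRA deltas) are bypassed, reproducing the base encoder
#'   bit-for-bit.
#' @return An `embedding_bundle`.
#' @export
encode_sequence <- function(model, tokens, adapters_enabled = TRUE) {
  stopifnot(inherits(model, "encoder"), model$config$kind == "sequence")
  seq_forward(model, tokens, adapters_enabled = adapters_enabled)
}

#' Encode a contact map
#'
#' Runs the patch transformer over a resized contact-map tensor; patch
#' embeddings are pooled over valid (non-padding) patches only.
#'
#' @param model A structure `encoder`.
#' @param map A `struct_input` from [resize_for_encoder()].
#' @return An `embedding_bundle`.
#' @export
encode_structure <- function(model, map) {
  stopifnot(inherits(model, "encoder"), model$config$kind == "structure")
  str_forward(model, map)
}

#' Project a protein-level embedding to the shared 256-d space
#'
#' Applies the encoder's modality-specific two-layer projector (dense, ReLU,
#' dense; output dimension 256).
#'
#' @param model An `encoder` (owns the projector weights for its modality).
#' @param protein_embedding Numeric vector of length `embed_dim`.
#' @return Numeric vector of length `proj_dim` (256).
#' @export
project <- function(model, protein_embedding) {
  stopifnot(inherits(model, "encoder"))
  if (length(protein_embedding) != model$config$embed_dim)
    stop("project: embedding has length ", length(protein_embedding),
         ", expected ", model$config$embed_dim)
  proj_fwd(model, protein_embedding)$y
}

#' @export
print.embedding_bundle <- function(x, ...) {
  cat("<embedding_bundle> ", x$modality, ": ", nrow(x$residue_embeddings),
      " x ", ncol(x$residue_embeddings), " residue embeddings, projected ",
      length(x$projected), "-d\n", sep = "")
  invisible(x)
}

#' Save / load a model checkpoint
#'
#' A checkpoint is a single-file archive of configs plus weights (and any
#' attached adaptation state). Loading restores a bit-identical model.
#'
#' @param object Any model object (an `encoder`, or a list of encoders as
#'   produced by [pretrain()]).
#' @param path Checkpoint file path.
#' @return `path` invisibly for save; the restored object for load.
#' @export
save_checkpoint <- function(object, path) {
  saveRDS(object, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) readRDS(path)
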
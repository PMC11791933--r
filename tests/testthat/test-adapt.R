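test_that("lora_forward implements the scaled low-rank update", {
  # scalar case: 2*1 + (8/2) * 1*3*1 = 14
  expect_equal(lora_forward(1, W0 = 2, A = 3, B = 1, alpha = 8, r = 2), 14)
  set.seed(1)
  W0 <- matrix(rnorm(12), 4, 3); A <- matrix(rnorm(6), 2, 3)
  B <- matrix(rnorm(8), 4, 2); x <- rnorm(3)
  expect_equal(lora_forward(x, W0, A, B * 0, alpha = 8, r = 2),
               drop(W0 %*% x))                       # zero-init start
  expect_equal(lora_forward(numeric(3), W0, A, B, 8, 2), rep(0, 4))
  # alpha = r reduces to (W0 + BA) x
  expect_equal(lora_forward(x, W0, A, B, alpha = 2, r = 2),
               drop((W0 + B %*% A) %*% x))
  # decomposition rank above min(d, k) violates the low-rank contract
  A3 <- matrix(rnorm(12), 4, 3); B3 <- matrix(rnorm(16), 4, 4)
  expect_error(lora_forward(x, W0, A3, B3, 8, 4), "rank")
})

test_that("adapter_forward computes the bottleneck increment", {
  # scalar: 3 * relu(2*1 - 1) + 0.5 = 3.5
  expect_equal(adapter_forward(1, W_down = 2, b_down = -1,
                               W_up = 3, b_up = 0.5), 3.5)
  set.seed(2)
  h <- rnorm(6); Wd <- matrix(rnorm(18), 3, 6); Wu <- matrix(rnorm(18), 6, 3)
  expect_equal(adapter_forward(h, Wd, rep(0, 3), Wu * 0, rep(0, 6)),
               rep(0, 6))                            # identity after skip
  # all-negative pre-activation passes only b_up through
  bu <- rnorm(6)
  expect_equal(adapter_forward(h, Wd * 0, rep(-1, 3), Wu, bu), bu)
})

test_that("merge_parallel sums increments over a shared skip", {
  set.seed(3)
  h <- rnorm(4)
  zero_ad <- list(W_down = matrix(0, 2, 4), b_down = rep(0, 2),
                  W_up = matrix(0, 4, 2), b_up = rep(0, 4))
  expect_equal(merge_parallel(h, list(zero_ad)), h)
  a1 <- list(W_down = matrix(rnorm(8), 2, 4), b_down = rnorm(2),
             W_up = matrix(rnorm(8), 4, 2), b_up = rnorm(4))
  a2 <- list(W_down = matrix(rnorm(8), 2, 4), b_down = rnorm(2),
             W_up = matrix(rnorm(8), 4, 2), b_up = rnorm(4), trainable = TRUE)
  u <- adapter_forward(h, a1$W_down, a1$b_down, a1$W_up, a1$b_up)
  v <- adapter_forward(h, a2$W_down, a2$b_down, a2$W_up, a2$b_up)
  expect_equal(merge_parallel(h, list(a1, a2)), h + u + v)
  # at most one trainable adapter; shapes must agree
  a1$trainable <- TRUE
  expect_error(merge_parallel(h, list(a1, a2)), "one adapter")
  bad <- list(W_down = matrix(0, 2, 5), b_down = rep(0, 2),
              W_up = matrix(0, 5, 2), b_up = rep(0, 5))
  expect_error(merge_parallel(h, list(zero_ad, bad)), "mismatch")
})

test_that("apply_strategy freezes and unfreezes the right components", {
  m <- tiny_seq_encoder()
  expect_error(apply_strategy(m, adaptation_spec("finetune_topK", K = 3L)),
               "exceeds n_layers")
  # full fine-tune limit: everything trainable
  mf <- apply_strategy(m, adaptation_spec("finetune_topK", K = 2L))
  expect_true(all(mf$trainable))
  # partial: only the top layer's internal parameters
  m1 <- apply_strategy(m, adaptation_spec("finetune_topK", K = 1L))
  tr <- names(m1$trainable)[m1$trainable]
  expect_true(all(grepl("^l2\\.", tr)))
  expect_false(m1$trainable[["tok_emb"]])
  expect_false(m1$trainable[["proj.W1"]])
  # lora: only A/B matrices of the targeted projections
  ml <- apply_strategy(m, adaptation_spec("lora", K = 1L, r = 2L))
  tr <- names(ml$trainable)[ml$trainable]
  expect_true(all(grepl("^l2\\.lora\\.", tr)))
  expect_length(tr, 8L)                       # 4 targets x {A, B}
  # adapter: only the designated trainable adapter
  ma <- apply_strategy(m, adaptation_spec("adapter", K = 2L, n_parallel = 2L,
                                          trainable_adapter = 2L))
  tr <- names(ma$trainable)[ma$trainable]
  expect_true(all(grepl("\\.ad[12]\\.a2\\.", tr)))
  expect_true(any(grepl("\\.ad[12]\\.a1\\.", names(ma$params))))
  expect_error(adaptation_spec("lora", targets = character(0)), "targets")
})

test_that("count_trainable agrees with the closed-form profile count", {
  cfg <- encoder_config("tiny", "sequence")
  specs <- list(
    adaptation_spec("finetune_topK", K = 1L),
    adaptation_spec("finetune_topK", K = 2L),
    adaptation_spec("lora", K = 2L, r = 3L),
    adaptation_spec("adapter", K = 1L, bottleneck = 8L))
  for (spec in specs) {
    m <- apply_strategy(init_encoder(cfg, seed = 1), spec)
    for (head in list(NULL, 10L)) {
      expect_equal(count_trainable(m, head_out = head)$trainable,
                   count_trainable_profile(cfg, spec, head_out = head),
                   info = spec$strategy)
    }
  }
  rep_ <- count_trainable(apply_strategy(init_encoder(cfg, 1), specs[[3]]))
  expect_equal(rep_$trainable + rep_$frozen, rep_$total)
})

test_that("full-profile accounting reproduces the published counts", {
  cfg <- encoder_config("full", "sequence")
  ft <- adaptation_spec("finetune_topK", K = 2L)
  # top-2 fine-tune plus GO heads: 42M / 40M / 40M at printed precision
  expect_equal(round(count_trainable_profile(cfg, ft, 1943L) / 1e6), 42)
  expect_equal(round(count_trainable_profile(cfg, ft, 489L) / 1e6), 40)
  expect_equal(round(count_trainable_profile(cfg, ft, 320L) / 1e6), 40)
  lo <- adaptation_spec("lora", K = 16L, r = 2L, alpha = 8)
  # LoRA encoder side: 16 layers x 4 targets x 2 * 1280 * 2
  expect_equal(count_trainable_profile(cfg, lo), 327680L)
  expect_equal(round(count_trainable_profile(cfg, lo, 1943L) / 1e6), 3)
  expect_equal(round(count_trainable_profile(cfg, lo, 489L) / 1e6), 1)
  expect_equal(round(count_trainable_profile(cfg, lo, 320L) / 1e6, 1), 0.7)
})

test_that("frozen parameters never move during training", {
  recs <- small_corpus(seed = 21, n_families = 2L, per = 3L)
  m <- apply_strategy(tiny_seq_encoder(), adaptation_spec("lora", K = 1L),
                      seed = 5)
  strm <- tiny_str_encoder()
  res <- pretrain(recs, m, strm,
                  pretrain_config(batch_size = 3L, epochs = 1L, seed = 1,
                                  lr_max = 0.05, max_len = 64L))
  frozen <- names(m$trainable)[!m$trainable]
  for (nm in frozen)
    expect_identical(res$seq_model$params[[nm]], m$params[[nm]])
  moved <- vapply(names(m$trainable)[m$trainable], function(nm)
    !identical(res$seq_model$params[[nm]], m$params[[nm]]), TRUE)
  expect_true(any(moved))
})
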
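# exhaustive-threshold brute-force oracle for Fmax, written directly from
# the protein-centric definition
oracle_fmax <- function(scores, truth, thresholds) {
  best <- 0
  for (t in thresholds) {
    prs <- c(); rcs <- c()
    any_pred <- FALSE
    for (i in seq_len(nrow(scores))) {
      pred <- which(scores[i, ] >= t & scores[i, ] > 0)
      tp <- length(intersect(pred, which(truth[i, ] == 1)))
      if (length(pred) > 0) {
        prs <- c(prs, tp / length(pred))
        any_pred <- TRUE
      }
      rcs <- c(rcs, tp / sum(truth[i, ]))
    }
    if (!any_pred) next
    pr <- mean(prs); rc <- mean(rcs)
    if (pr + rc > 0) best <- max(best, 2 * pr * rc / (pr + rc))
  }
  best
}

test_that("focal loss matches its closed forms", {
  expect_equal(focal_loss(c(0, 1), target = 2, gamma = 2), 0)   # p_t = 1
  expect_equal(focal_loss(c(0.5, 0.5), target = 1, gamma = 2),
               0.25 * log(2), tolerance = 1e-12)
  # gamma = 0 reduces to cross-entropy on random simplexes
  set.seed(5)
  P <- matrix(rexp(40), 8); P <- P / rowSums(P)
  tgt <- sample(5, 8, replace = TRUE)
  ce <- mean(-log(P[cbind(1:8, tgt)]))
  expect_equal(focal_loss(P, tgt, gamma = 0), ce, tolerance = 1e-8)
  expect_error(focal_loss(c(0.5, 0.5), 1, gamma = -1))
})

test_that("multilabel BCE matches hand-computed values", {
  expect_equal(multilabel_bce(0, 1), log(2), tolerance = 1e-12)
  expect_equal(multilabel_bce(0, 0), log(2), tolerance = 1e-12)
  expect_lt(multilabel_bce(30, 1), 1e-12)      # confident and correct
  # 2-label hand example: mean of -log sigmoid(1), -log(1 - sigmoid(-2))
  z <- matrix(c(1, -2), 1); y <- matrix(c(1, 0), 1)
  want <- mean(c(-log(plogis(1)), -log(1 - plogis(-2))))
  expect_equal(multilabel_bce(z, y), want, tolerance = 1e-12)
})

test_that("fmax matches the brute-force oracle and its degenerate cases", {
  truth <- rbind(c(1, 0, 1, 0),
                 c(0, 1, 0, 0),
                 c(1, 1, 0, 1))
  expect_equal(fmax(truth, truth), 1.0)
  expect_equal(fmax(truth * 0, truth), 0)
  scores <- rbind(c(0.9, 0.1, 0.6, 0.2),
                  c(0.3, 0.8, 0.2, 0.4),
                  c(0.7, 0.5, 0.1, 0.9))
  grid <- seq(0, 1, by = 0.1)
  expect_equal(fmax(scores, truth, grid), oracle_fmax(scores, truth, grid))
  grid <- seq(0, 1, by = 0.01)
  expect_equal(fmax(scores, truth, grid), oracle_fmax(scores, truth, grid))
  expect_error(fmax(scores, truth * 0), "positive truth")
  # invariant to a strictly monotone transform on a value-adapted grid
  mono <- sqrt(scores)
  g1 <- sort(unique(c(0, scores, 1)))
  g2 <- sort(unique(c(0, mono, 1)))
  expect_equal(fmax(scores, truth, g1), fmax(mono, truth, g2))
})

test_that("residue accuracy respects the mask", {
  expect_equal(residue_accuracy(c(1, 2, 3), c(1, 2, 3)), 100)
  expect_equal(residue_accuracy(c(1, 2, 1, 2), c(1, 1, 2, 2)), 50)
  pred <- c(1, 2, 3, 9, 9)
  true <- c(1, 2, 3, 1, 1)
  mask <- c(TRUE, TRUE, TRUE, FALSE, FALSE)
  expect_equal(residue_accuracy(pred, true, mask), 100)
  pred[4:5] <- c(5, 6)                          # flipping padding: no change
  expect_equal(residue_accuracy(pred, true, mask), 100)
  expect_error(residue_accuracy(pred, true, rep(FALSE, 5)), "empty mask")
})

test_that("a dense head reaches 100% on linearly separable embeddings", {
  set.seed(8)
  n <- 30
  X <- rbind(matrix(rnorm(n * 4, mean = 3), n),
             matrix(rnorm(n * 4, mean = -3), n))
  y <- rep(1:2, each = n)
  spec <- task_head_spec("custom", out_dim = 2L)
  head <- train_head(X, y, spec, epochs = 300L, lr = 0.5)
  pred <- predict_head(head, X)
  expect_equal(mean(pred$class == y), 1)
  expect_lt(tail(head$history, 1), head$history[1])
  # zero-epoch training leaves the untrained baseline
  h0 <- train_head(X, y, spec, epochs = 0L, seed = 3)
  h0b <- train_head(X, y, spec, epochs = 0L, seed = 3)
  expect_identical(h0$W, h0b$W)
})

test_that("convex head training is insensitive to its seed", {
  set.seed(9)
  X <- rbind(matrix(rnorm(40, mean = 1.5), 10),
             matrix(rnorm(40, mean = -1.5), 10))
  y <- rep(1:2, each = 10)
  spec <- task_head_spec("custom", out_dim = 2L)
  h1 <- train_head(X, y, spec, epochs = 2000L, lr = 0.3, gamma = 0, seed = 1)
  h2 <- train_head(X, y, spec, epochs = 2000L, lr = 0.3, gamma = 0, seed = 99)
  expect_equal(tail(h1$history, 1), tail(h2$history, 1), tolerance = 1e-3)
  expect_equal(predict_head(h1, X)$probs, predict_head(h2, X)$probs,
               tolerance = 0.05)
})

test_that("multilabel heads train under BCE", {
  set.seed(10)
  X <- rbind(matrix(rnorm(40, 2), 10), matrix(rnorm(40, -2), 10))
  Y <- matrix(0, 20, 3)
  Y[1:10, 1] <- 1; Y[11:20, 2] <- 1; Y[, 3] <- rep(c(1, 0), 10)
  spec <- task_head_spec("custom", out_dim = 3L, loss = "bce_multilabel")
  head <- train_head(X, Y, spec, epochs = 300L, lr = 0.5)
  expect_lt(tail(head$history, 1), head$history[1])
  sc <- predict_head(head, X)$scores
  expect_gt(fmax(sc, Y), 0.8)
})

test_that("encoder fine-tuning trains the head and honours strategies", {
  recs <- small_corpus(seed = 51, n_families = 2L, per = 5L)
  y <- as.integer(factor(vapply(recs, `[[`, "", "family")))
  base <- tiny_seq_encoder(seed = 60)
  spec <- task_head_spec("custom", out_dim = 2L, max_len = 64L)
  # frozen encoder: only the head trains
  fit <- finetune_encoder(base, recs, y, spec, strategy = NULL,
                          epochs = 30L, lr = 0.5)
  expect_identical(fit$model$params, base$params)
  expect_lt(tail(fit$history, 1), fit$history[1])
  X <- embedding_matrix(fit$model, recs, max_len = 64L)
  expect_gt(mean(predict_head(fit$head, X)$class == y), 0.9)
  # LoRA strategy: base weights frozen, deltas train
  fit2 <- finetune_encoder(base, recs, y, spec,
                           strategy = adaptation_spec("lora", K = 1L),
                           epochs = 3L, lr = 0.1)
  expect_identical(fit2$model$params[["l2.attn.Wq"]],
                   base$params[["l2.attn.Wq"]])
  expect_false(identical(fit2$model$params[["l2.lora.query.B"]] * 0,
                         fit2$model$params[["l2.lora.query.B"]]))
})
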
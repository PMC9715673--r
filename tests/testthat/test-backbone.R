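test_that("backbone contracts: penultimate widths and input validation", {
  tiny <- build_backbone("tiny")
  expect_identical(tiny$feature_dim, 64L)
  expect_identical(tiny$input_spec, c(96L, 96L, 1L))
  dn <- build_backbone("densenet121")
  expect_identical(dn$feature_dim, 1024L)
  expect_identical(dn$input_spec, c(224L, 224L, 3L))
  expect_error(build_backbone("resnet"), "unknown architecture")
  expect_error(build_backbone("tiny", input_spec = c(96, 96, 0)), "channels")
  expect_error(build_backbone("tiny", input_spec = c(16, 16, 1)), ">= 32")
})

test_that("forward pass yields a probability and deterministic features", {
  m <- build_backbone("tiny", input_spec = c(32, 32, 1), seed = 4)
  img <- matrix(runif(32 * 32), 32, 32)
  p <- predict_prob(m, img)
  expect_gt(p, 0); expect_lt(p, 1)
  f1 <- extract_features(m, img)
  f2 <- extract_features(m, img)
  expect_identical(f1, f2)
  expect_length(f1, 64L)
  expect_error(extract_features(m, array(runif(32 * 32 * 2), c(32, 32, 2))),
               "channels")
})

test_that("weighted binary cross-entropy matches closed forms", {
  expect_lt(weighted_bce(1, 1 - 1e-9), 1e-6)
  expect_equal(weighted_bce(0, 0.5), log(2), tolerance = 1e-12)
  expect_error(weighted_bce(2, 0.5), "labels")
  # inverse-frequency weighting: 90 negatives, 10 positives
  labs <- c(rep(0, 90), rep(1, 10))
  w <- class_weights(labs)
  expect_equal(w[2] / w[1], 9, tolerance = 1e-12)
  expect_equal(w, c(100 / 180, 100 / 20), tolerance = 1e-12)
  # mixed batch against hand arithmetic
  y <- c(1, 0, 1)
  p <- c(0.8, 0.3, 0.6)
  hand <- c(-w[2] * log(0.8), -w[1] * log(0.7), -w[2] * log(0.6))
  expect_equal(unname(weighted_bce(y, p, w)), hand, tolerance = 1e-12)
  expect_error(class_weights(rep(1, 5)), "both classes")
})

test_that("F1 matches the confusion-matrix definition", {
  expect_identical(f1_score(c(0.9, 0.1, 0.8), c(1, 0, 1)), 1)
  # TP = 8, FP = 2, FN = 2
  preds <- c(rep(0.9, 10), rep(0.1, 2))
  labs <- c(rep(1, 8), rep(0, 2), rep(1, 2))
  expect_equal(f1_score(preds, labs), 0.8, tolerance = 1e-12)
  # TP = 3, FP = 1, FN = 2
  preds <- c(rep(0.9, 4), rep(0.1, 2))
  labs <- c(1, 1, 1, 0, 1, 1)
  expect_equal(f1_score(preds, labs), 2 * 0.75 * 0.6 / 1.35, tolerance = 1e-12)
  expect_identical(f1_score(c(0.1, 0.2), c(1, 1)), 0)
  expect_error(f1_score(numeric(0), numeric(0)), "empty")
  # oracle equivalence on random vectors: F1 = 2TP / (2TP + FP + FN)
  set.seed(99)
  for (i in 1:100) {
    pr <- runif(30)
    lb <- rbinom(30, 1, 0.5)
    yhat <- as.integer(pr >= 0.5)
    tp <- sum(yhat & lb); fp <- sum(yhat & !lb); fn <- sum(!yhat & lb)
    oracle <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
    expect_equal(f1_score(pr, lb), oracle, tolerance = 1e-12)
  }
})

test_that("analytic gradients match finite differences", {
  ns <- asNamespace("saliret")
  m <- build_backbone("tiny", input_spec = c(32, 32, 1), seed = 2)
  set.seed(11)
  x <- array(runif(32 * 32), c(32, 32, 1))
  p <- ns$get_params(m)
  fw <- ns$model_forward(m, x)
  g <- ns$model_backward(m, fw, fw$prob - 1)
  pf <- unlist(p); gf <- unlist(g)
  expect_length(gf, length(pf))
  loss_at <- function(v) {
    m2 <- ns$set_params(m, utils::relist(v, p))
    weighted_bce(1, ns$model_forward(m2, x)$prob)
  }
  idx <- sample(length(pf), 15)
  for (i in idx) {
    e <- 1e-5
    a <- pf; a[i] <- a[i] + e
    b <- pf; b[i] <- b[i] - e
    expect_equal(unname(gf[i]), (loss_at(a) - loss_at(b)) / (2 * e),
                 tolerance = 1e-4)
  }
})

test_that("training selects the best-F1 epoch and is seed-reproducible", {
  samples <- small_phantoms(24, seed = 7)
  tr <- samples[1:16]
  va <- samples[17:24]
  m <- build_backbone("tiny", input_spec = c(32, 32, 1), seed = 1)
  cfg <- train_config(epochs = 3, batch_size = 8, optimizer = "adam",
                      learning_rate = 1e-3, seed = 5)
  fit <- train(m, tr, va, cfg)
  expect_identical(nrow(fit$log), 3L)
  expect_identical(sum(fit$log$selected), 1L)
  sel <- fit$log$epoch[fit$log$selected]
  expect_gte(fit$log$val_f1[sel], max(fit$log$val_f1) - 1e-12)
  # ties go to the earlier epoch
  expect_identical(sel, fit$log$epoch[which.max(fit$log$val_f1)])
  # selected model reproduces the logged validation F1
  val_p <- vapply(va, function(s) predict_prob(fit$model, s$image), 1.0)
  expect_equal(f1_score(val_p, vapply(va, `[[`, 1L, "label")),
               max(fit$log$val_f1), tolerance = 1e-12)
  # bit-identical rerun
  fit2 <- train(build_backbone("tiny", input_spec = c(32, 32, 1), seed = 1),
                tr, va, cfg)
  expect_identical(fit$log, fit2$log)

  one <- train(build_backbone("tiny", input_spec = c(32, 32, 1), seed = 1),
               tr, va, train_config(epochs = 1, batch_size = 8, seed = 5))
  expect_identical(one$log$selected, TRUE)
})

test_that("warm start copies weights and rejects mismatched shapes", {
  ns <- asNamespace("saliret")
  samples <- small_phantoms(16, seed = 3)
  base <- build_backbone("tiny", input_spec = c(32, 32, 1), seed = 1)
  donor <- build_backbone("tiny", input_spec = c(32, 32, 1), seed = 99)
  fit <- train(base, samples[1:10], samples[11:16],
               train_config(epochs = 1, batch_size = 4, init_from = donor,
                            seed = 2, aug_rotate = 0, aug_translate = 0))
  expect_true(fit$model$trained)
  other <- build_backbone("tiny", input_spec = c(32, 32, 1), feature_dim = 32,
                          seed = 1)
  expect_error(
    train(other, samples[1:10], samples[11:16],
          train_config(epochs = 1, init_from = donor, seed = 2)),
    "checkpoint")
  # single-class training data with class weighting
  pos <- samples[vapply(samples, `[[`, 1L, "label") == 1L]
  expect_error(train(base, pos, samples[1:4],
                     train_config(epochs = 1, seed = 1)), "both classes")
})

test_that("checkpoints round-trip with sidecar metadata", {
  m <- build_backbone("tiny", input_spec = c(32, 32, 1), seed = 6)
  m$meta$selected_epoch <- 2L
  m$meta$fingerprint <- saliret:::model_fingerprint(m)
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(m, path)
  back <- load_checkpoint(path)
  img <- matrix(runif(32 * 32), 32, 32)
  expect_identical(extract_features(back, img), extract_features(m, img))
  side <- jsonlite::read_json(paste0(path, ".json"))
  expect_identical(side$architecture_id, "tiny")
  expect_identical(side$feature_dim, 64L)
  expect_false(side$attention)
  expect_error(load_checkpoint(file.path(tempdir(), "nope.rds")), "not found")
})
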
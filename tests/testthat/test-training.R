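sep_split <- function(n = 200L, D = 8L, seed = 1L, sigma = 0.05) {
  dom <- gen_embedding_domain(domain_spec("sep", n, pos_ratio = 0.25,
                                          dim = D, delta = 2, sigma = sigma,
                                          seed = seed))
  split_domain(dom, seed = seed + 1L)
}

quick_cfg <- function(seed = 1L, ...) {
  train_config(max_epochs = 50L, plateau_patience = 3L,
               early_stop_patience = 6L, seed = seed, ...)
}

test_that("training reaches a perfect ranking on separable data", {
  data <- sep_split(seed = 71L)
  init <- init_classifier(8L, seed = 71L)
  fit <- suppressMessages(train_classifier(init, data, quick_cfg(71L)))
  expect_equal(max(fit$history$val_auprc), 1.0)
  expect_lte(nrow(fit$history), 50L)
})

test_that("permuted labels score at chance level on held-out data", {
  # the held-out test part gives the unbiased chance-level read (validation
  # AUPRC is maximized by model selection, so it sits above prevalence by
  # construction)
  aups <- sapply(1:5, function(s) {
    data <- sep_split(n = 500L, seed = 80L + s)
    set.seed(s)
    data$train$y <- sample(data$train$y)
    data$validation$y <- sample(data$validation$y)
    data$test$y <- sample(data$test$y)
    init <- init_classifier(8L, seed = s)
    fit <- suppressMessages(train_classifier(
      init, data, train_config(max_epochs = 15L, plateau_patience = 3L,
                               early_stop_patience = 5L, seed = s)))
    pred <- predict_classifier(fit$params, data$test$X)
    auprc(data$test$y, pred$prob)
  })
  prevalence <- 0.25
  expect_lt(abs(mean(aups) - prevalence), 0.1)
})

test_that("single-class training or validation parts are rejected", {
  data <- sep_split(seed = 73L)
  bad <- data
  bad$train$y <- rep(0, length(bad$train$y))
  expect_error(suppressMessages(train_classifier(
    init_classifier(8L, seed = 1L), bad, quick_cfg())), "single class")
})

test_that("model selection returns the epoch with the best validation AUPRC", {
  data <- sep_split(seed = 74L, sigma = 1.5)
  init <- init_classifier(8L, seed = 74L)
  cfg <- quick_cfg(74L)
  fit <- suppressMessages(train_classifier(init, data, cfg))
  pred <- predict_classifier(fit$params, data$validation$X)
  got <- auprc(data$validation$y, pred$prob)
  # the returned checkpoint attains the best monitored value (epoch 0 = the
  # initial parameters count as a candidate)
  expect_gte(got + 1e-12, max(fit$history$val_auprc))
  if (fit$best_epoch > 0L) {
    expect_equal(got, fit$history$val_auprc[fit$best_epoch], tolerance = 1e-12)
  }
  # early stopping: no more than patience epochs after the best one
  expect_lte(nrow(fit$history),
             max(fit$best_epoch, 1L) + cfg$early_stop_patience)
})

test_that("learning rate is non-increasing and halves at plateau events", {
  data <- sep_split(seed = 75L, sigma = 2)
  fit <- suppressMessages(train_classifier(
    init_classifier(8L, seed = 75L), data,
    train_config(max_epochs = 30L, plateau_patience = 2L,
                 early_stop_patience = 8L, seed = 75L)))
  lr <- fit$history$lr
  expect_true(all(diff(lr) <= 0))
  drops <- which(diff(lr) < 0)
  for (d in drops) expect_equal(lr[d + 1L] / lr[d], 0.5, tolerance = 1e-12)
})

test_that("training is bit-identical under identical config and seed", {
  data <- sep_split(seed = 76L, sigma = 1)
  init <- init_classifier(8L, seed = 76L)
  f1 <- suppressMessages(train_classifier(init, data, quick_cfg(76L)))
  f2 <- suppressMessages(train_classifier(init, data, quick_cfg(76L)))
  expect_identical(f1$history, f2$history)
  expect_identical(f1$params, f2$params)
})

test_that("frozen GRU layers are bit-identical after fine-tuning", {
  data <- sep_split(seed = 77L, sigma = 1)
  init <- init_classifier(8L, n_layers = 3L, seed = 77L)
  base <- suppressMessages(train_classifier(
    init, data, train_config(max_epochs = 5L, seed = 77L)))$params
  frozen <- copy_and_freeze(base, freeze_gru = TRUE)
  fit <- suppressMessages(train_classifier(
    frozen, data, train_config(max_epochs = 5L, seed = 78L)))
  for (l in seq_along(base$layers)) {
    expect_identical(fit$params$layers[[l]], base$layers[[l]])
  }
  # without freezing the discriminator AND the recurrent stack both move
  free <- suppressMessages(train_classifier(
    copy_and_freeze(base, freeze_gru = FALSE), data,
    train_config(max_epochs = 5L, seed = 78L)))
  expect_false(identical(free$params$layers[[1L]], base$layers[[1L]]))
  expect_false(identical(free$params$disc$W2, base$disc$W2))
})

test_that("strategy dispatch matches the four definitions", {
  dom_pre <- gen_embedding_domain(domain_spec("pre", 400L, pos_ratio = 0.25,
                                              dim = 8L, seed = 90L))
  dom_sp <- gen_embedding_domain(domain_spec("sp", 150L, pos_ratio = 0.25,
                                             dim = 8L, theta = 0.3,
                                             seed = 91L))
  pre <- split_domain(dom_pre, seed = 92L)
  sp <- split_domain(dom_sp, seed = 93L)
  init <- init_classifier(8L, n_layers = 2L, seed = 94L)
  cfg <- train_config(max_epochs = 5L, seed = 95L)

  spfit <- suppressMessages(run_strategy("SP", pre, sp, init, cfg))
  # zero-epoch fine-tuning returns the supervised pre-training checkpoint
  zero <- train_config(max_epochs = 0L, seed = 96L)
  ts0 <- suppressMessages(run_strategy("TSTL", pre, sp, init, cfg,
                                       finetune_cfg = zero,
                                       base_params = spfit$params))
  expect_identical(ts0$params$layers, spfit$params$layers)
  expect_identical(ts0$params$disc, spfit$params$disc)

  # GM with an empty pre-training set behaves exactly like DT
  empty <- list(train = list(X = pre$train$X[0, , drop = FALSE], y = numeric(0)),
                validation = list(X = pre$validation$X[0, , drop = FALSE],
                                  y = numeric(0)))
  gm <- suppressMessages(run_strategy("GM", empty, sp, init, cfg))
  dt <- suppressMessages(run_strategy("DT", NULL, sp, init, cfg))
  expect_identical(gm$history, dt$history)
  expect_identical(gm$params, dt$params)

  expect_error(suppressMessages(run_strategy("TSTL", NULL, sp, init, cfg)),
               "pre-training")
})

test_that("compare_strategies emits one row per strategy", {
  dom_pre <- gen_embedding_domain(domain_spec("pre", 300L, pos_ratio = 0.25,
                                              dim = 8L, seed = 97L))
  dom_sp <- gen_embedding_domain(domain_spec("sp", 120L, pos_ratio = 0.25,
                                             dim = 8L, theta = 0.3,
                                             seed = 98L))
  tab <- suppressMessages(compare_strategies(
    split_domain(dom_pre, seed = 1L), split_domain(dom_sp, seed = 2L),
    init_classifier(8L, n_layers = 2L, seed = 3L),
    train_config(max_epochs = 4L, seed = 4L)))
  expect_equal(tab$strategy, c("DT", "SP", "GM", "TSTL"))
  expect_true(all(c("bacc", "mcc", "auc", "auprc") %in% names(tab)))
  expect_true(all(tab$auprc >= 0 & tab$auprc <= 1))
})

test_that("transfer gain holds on the default benchmark (seed-averaged)", {
  res <- benchmark_results(5L)$auprc
  expect_gt(mean(res[, "TSTL"] - res[, "DT"]), 0)
})

test_that("cross-domain matrix measures AUPRC increments", {
  mk <- function(theta, seed) {
    gen_embedding_domain(domain_spec(paste0("d", seed), 600L,
                                     pos_ratio = 0.25, dim = 8L,
                                     theta = theta, seed = seed))
  }
  cfg <- train_config(max_epochs = 10L, seed = 5L)
  fit_on <- function(dom, seed) {
    sp <- split_domain(dom, seed = seed)
    list(model = suppressMessages(train_classifier(
      init_classifier(8L, n_layers = 2L, seed = seed), sp, cfg))$params,
      test = sp$test)
  }
  one <- fit_on(mk(0, 201L), 11L)
  m1 <- cross_domain_matrix(list(a = one$model), list(a = one$test))
  expect_equal(m1, matrix(0, 1, 1, dimnames = list("a", "a")))

  # identical generator seeds: models a and b are exchangeable, so the
  # signed off-diagonal increments average out to ~0 over seeds
  gaps_same <- sapply(1:5, function(s) {
    d <- mk(0, 300L + s)
    fa <- fit_on(d, 20L + s); fb <- fit_on(d, 40L + s)
    m <- cross_domain_matrix(list(a = fa$model, b = fb$model),
                             list(a = fa$test, b = fb$test))
    mean(m[upper.tri(m) | lower.tri(m)])
  })
  expect_lt(abs(mean(gaps_same)), 0.05)

  # orthogonal discriminative directions: transfer strictly degraded
  gaps_far <- sapply(1:5, function(s) {
    fa <- fit_on(mk(0, 400L + s), 60L + s)
    fb <- fit_on(mk(pi / 2, 500L + s), 80L + s)
    m <- cross_domain_matrix(list(a = fa$model, b = fb$model),
                             list(a = fa$test, b = fb$test))
    mean(m[upper.tri(m) | lower.tri(m)])
  })
  expect_lt(mean(gaps_far), 0)
})
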
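# Training loop (Adam, AUPRC-monitored early stopping, plateau learning-rate
# reduction) and the four training/transfer strategies DT / SP / GM / TSTL.

#' Training configuration
#'
#' Repo defaults; the monitor is always validation AUPRC (the primary metric
#' on imbalanced data), validation loss is logged but never used for model
#' selection.
#'
#' @param max_epochs Maximum number of epochs (0 returns the initial
#'   parameters untouched).
#' @param batch_size Mini-batch size.
#' @param initial_lr Initial Adam learning rate.
#' @param plateau_factor Learning-rate multiplier applied after
#'   `plateau_patience` non-improving epochs, in (0, 1).
#' @param plateau_patience Epochs without validation-AUPRC improvement before
#'   the learning rate is reduced.
#' @param early_stop_patience Epochs without improvement before training
#'   stops.
#' @param seed Integer seed controlling shuffling (and thereby the whole
#'   run).
#' @param strategy One of `"DT"`, `"SP"`, `"GM"`, `"TSTL"` (used by
#'   [run_strategy()]).
#' @param freeze_gru Freeze GRU layers during TSTL fine-tuning.
#' @param weight_both Use the both-terms loss weighting variant.
#' @param adam_beta1,adam_beta2,adam_eps Adam moment parameters.
#' @return List of class `train_config`.
#' @export
train_config <- function(max_epochs = 200L, batch_size = 64L,
                         initial_lr = 1e-3, plateau_factor = 0.5,
                         plateau_patience = 5L, early_stop_patience = 10L,
                         seed = 1L, strategy = c("DT", "SP", "GM", "TSTL"),
                         freeze_gru = FALSE, weight_both = FALSE,
                         adam_beta1 = 0.9, adam_beta2 = 0.999,
                         adam_eps = 1e-8) {
  strategy <- match.arg(strategy)
  stopifnot(plateau_patience >= 1L, early_stop_patience >= 1L,
            plateau_factor > 0, plateau_factor < 1, initial_lr > 0,
            batch_size >= 1L, max_epochs >= 0L)
  structure(as.list(environment()), class = "train_config")
}

# zero-filled gradient/moment structure matching the trainable leaves
zero_like <- function(params) {
  list(layers = lapply(params$layers, function(l) {
    lapply(l, function(t) if (is.matrix(t)) matrix(0, nrow(t), ncol(t))
           else numeric(length(t)))
  }),
  disc = lapply(params$disc[c("W1", "b1", "gamma", "beta", "W2", "b2")],
                function(t) if (is.matrix(t)) matrix(0, nrow(t), ncol(t))
                else numeric(length(t))))
}

adam_step <- function(params, grads, state, lr, cfg) {
  state$t <- state$t + 1L
  b1 <- cfg$adam_beta1; b2 <- cfg$adam_beta2
  c1 <- 1 - b1^state$t; c2 <- 1 - b2^state$t
  upd <- function(theta, g, m, v) {
    m <- b1 * m + (1 - b1) * g
    v <- b2 * v + (1 - b2) * g^2
    theta <- theta - lr * (m / c1) / (sqrt(v / c2) + cfg$adam_eps)
    list(theta = theta, m = m, v = v)
  }
  for (l in seq_along(params$layers)) {
    if (isTRUE(params$frozen_mask[l])) next
    for (nm in names(params$layers[[l]])) {
      u <- upd(params$layers[[l]][[nm]], grads$layers[[l]][[nm]],
               state$m$layers[[l]][[nm]], state$v$layers[[l]][[nm]])
      params$layers[[l]][[nm]] <- u$theta
      state$m$layers[[l]][[nm]] <- u$m
      state$v$layers[[l]][[nm]] <- u$v
    }
  }
  for (nm in names(grads$disc)) {
    u <- upd(params$disc[[nm]], grads$disc[[nm]],
             state$m$disc[[nm]], state$v$disc[[nm]])
    params$disc[[nm]] <- u$theta
    state$m$disc[[nm]] <- u$m
    state$v$disc[[nm]] <- u$v
  }
  list(params = params, state = state)
}

#' Train the classifier on a featurized split
#'
#' Adam optimization of the class-weighted binary cross-entropy with
#' `w = class_weight(pos_ratio)` recomputed from the training part. After
#' every epoch the validation AUPRC is evaluated (eval mode, deterministic);
#' the learning rate is multiplied by `plateau_factor` after
#' `plateau_patience` non-improving epochs and training stops after
#' `early_stop_patience` non-improving epochs or `max_epochs`. The returned
#' parameters are the best-epoch checkpoint, where the initial parameters
#' count as the epoch-0 candidate (so fine-tuning never returns a checkpoint
#' worse than its starting point on the monitored metric). Fully
#' reproducible from `cfg$seed`.
#'
#' @param params Initial `classifier_params`.
#' @param data List with `train` and `validation`, each `list(X, y)`.
#' @param cfg A [train_config()].
#' @return List with `params` (best checkpoint) and `history` (per-epoch
#'   data.frame: train_loss, val_loss, val_auprc, val_auc, val_bacc, lr) plus
#'   `best_epoch`.
#' @export
train_classifier <- function(params, data, cfg = train_config()) {
  X <- data$train$X; y <- data$train$y
  Xv <- data$validation$X; yv <- data$validation$y
  if (length(y) == 0L || length(yv) == 0L) {
    stop("train and validation parts must be nonempty")
  }
  if (length(unique(y)) < 2L) stop("training part contains a single class")
  if (length(unique(yv)) < 2L) stop("validation part contains a single class")
  pos_ratio <- mean(y)
  w <- class_weight(pos_ratio)
  message(sprintf("training: n = %d, pos_ratio = %.4f, w = %.3f",
                  length(y), pos_ratio, w))
  lr <- cfg$initial_lr
  state <- list(t = 0L, m = zero_like(params), v = zero_like(params))
  # The initial parameters are the epoch-0 candidate: model selection can
  # never return a checkpoint worse on validation AUPRC than its starting
  # point (this is what makes fine-tuning from a pretrained checkpoint safe
  # when the target validation set is small).
  val0 <- forward_batch(Xv, params, mode = "eval")
  best <- list(params = params, auprc = auprc(yv, val0$prob), epoch = 0L)
  hist <- list()
  plateau_wait <- 0L; stop_wait <- 0L
  with_seed(cfg$seed, {
    for (epoch in seq_len(cfg$max_epochs)) {
      idx <- sample.int(length(y))
      starts <- seq(1L, length(y), by = cfg$batch_size)
      epoch_loss <- 0
      for (s in starts) {
        take <- idx[s:min(s + cfg$batch_size - 1L, length(y))]
        Xb <- X[take, , drop = FALSE]; yb <- y[take]
        fwd <- forward_batch(Xb, params, mode = "train", keep_cache = TRUE)
        grads <- backward_batch(Xb, yb, w, params, fwd,
                                weight_both = cfg$weight_both)
        params <- update_bn_moments(params, fwd)
        st <- adam_step(params, grads, state, lr, cfg)
        params <- st$params; state <- st$state
        epoch_loss <- epoch_loss +
          weighted_bce(yb, fwd$prob, w, cfg$weight_both) * length(take)
      }
      val <- forward_batch(Xv, params, mode = "eval")
      val_auprc <- auprc(yv, val$prob)
      rep_ <- list(train_loss = epoch_loss / length(y),
                   val_loss = weighted_bce(yv, val$prob, w, cfg$weight_both),
                   val_auprc = val_auprc, val_auc = roc_auc(yv, val$prob),
                   val_bacc = bacc(confusion_counts(yv, val$prob)), lr = lr)
      hist[[epoch]] <- rep_
      if (val_auprc > best$auprc) {
        best <- list(params = params, auprc = val_auprc, epoch = epoch)
        plateau_wait <- 0L; stop_wait <- 0L
      } else {
        plateau_wait <- plateau_wait + 1L
        stop_wait <- stop_wait + 1L
        if (plateau_wait >= cfg$plateau_patience) {
          lr <- lr * cfg$plateau_factor
          plateau_wait <- 0L
        }
        if (stop_wait >= cfg$early_stop_patience) break
      }
    }
  })
  history <- if (length(hist)) {
    cbind(epoch = seq_along(hist),
          as.data.frame(do.call(rbind, lapply(hist, unlist))))
  } else {
    data.frame(epoch = integer(), train_loss = numeric(),
               val_loss = numeric(), val_auprc = numeric(),
               val_auc = numeric(), val_bacc = numeric(), lr = numeric())
  }
  list(params = best$params, history = history, best_epoch = best$epoch)
}

combine_xy <- function(a, b) {
  list(X = rbind(a$X, b$X), y = c(a$y, b$y))
}

#' Run one of the four training/transfer strategies
#'
#' * `DT` (direct training): train on the species data only.
#' * `SP` (supervised pre-training): train on the pre-training data only
#'   (evaluated later on the species test set).
#' * `GM` (general model): train on the concatenation of pre-training and
#'   species data, no fine-tuning.
#' * `TSTL` (two-stage transfer): train on the pre-training data, then
#'   fine-tune on the species data (optionally with frozen GRU layers via
#'   `finetune_cfg$freeze_gru`; a precomputed SP checkpoint can be supplied
#'   as `base_params` to avoid repeating the first stage).
#'
#' @param strategy `"DT"`, `"SP"`, `"GM"` or `"TSTL"`.
#' @param pretrain Featurized split of the pre-training dataset (may be NULL
#'   for DT).
#' @param species Featurized split of the target species dataset.
#' @param init Initial `classifier_params`.
#' @param cfg [train_config()] for the (first-stage) training run.
#' @param finetune_cfg [train_config()] for the TSTL fine-tuning stage;
#'   defaults to `cfg`.
#' @param base_params Optional pretrained checkpoint reused as the TSTL first
#'   stage.
#' @return List with `params`, `history` (fine-tuning history for TSTL),
#'   `strategy` and for TSTL also `pretrain_params`.
#' @export
run_strategy <- function(strategy, pretrain, species, init,
                         cfg = train_config(), finetune_cfg = cfg,
                         base_params = NULL) {
  strategy <- match.arg(strategy, c("DT", "SP", "GM", "TSTL"))
  message(sprintf("strategy %s", strategy))
  if (strategy == "DT") {
    out <- train_classifier(init, species, cfg)
  } else if (strategy == "SP") {
    out <- train_classifier(init, pretrain, cfg)
  } else if (strategy == "GM") {
    pooled <- if (is.null(pretrain) || length(pretrain$train$y) == 0L) {
      species
    } else {
      list(train = combine_xy(pretrain$train, species$train),
           validation = combine_xy(pretrain$validation, species$validation))
    }
    out <- train_classifier(init, pooled, cfg)
  } else {
    if (is.null(base_params)) {
      if (is.null(pretrain)) stop("TSTL requires pre-training data")
      base_params <- train_classifier(init, pretrain, cfg)$params
    }
    start <- copy_and_freeze(base_params,
                             freeze_gru = isTRUE(finetune_cfg$freeze_gru))
    ft <- train_classifier(start, species, finetune_cfg)
    out <- list(params = if (finetune_cfg$max_epochs > 0L) ft$params
                         else start,
                history = ft$history, best_epoch = ft$best_epoch)
    out$pretrain_params <- base_params
  }
  out$strategy <- strategy
  out
}

#' Evaluate a model on a labeled feature matrix
#'
#' @param params `classifier_params`.
#' @param X Feature matrix.
#' @param y Binary labels.
#' @param threshold Confusion threshold.
#' @return A [metrics_report()].
#' @export
evaluate_classifier <- function(params, X, y, threshold = 0.5) {
  pred <- predict_classifier(params, X)
  metrics_report(y, pred$prob, threshold)
}

#' Compare the four strategies on one pretrain/species pair
#'
#' Trains DT, SP, GM and TSTL from the same initialization and evaluates each
#' on the species test part.
#'
#' @param pretrain,species Featurized splits.
#' @param init Initial `classifier_params`.
#' @param cfg,finetune_cfg Configurations, see [run_strategy()].
#' @return data.frame with one row per strategy and columns bacc, mcc, auc,
#'   auprc.
#' @export
compare_strategies <- function(pretrain, species, init,
                               cfg = train_config(), finetune_cfg = cfg) {
  sp <- run_strategy("SP", pretrain, species, init, cfg)
  fits <- list(
    DT = run_strategy("DT", pretrain, species, init, cfg),
    SP = sp,
    GM = run_strategy("GM", pretrain, species, init, cfg),
    TSTL = run_strategy("TSTL", pretrain, species, init, cfg, finetune_cfg,
                        base_params = sp$params))
  rows <- lapply(names(fits), function(nm) {
    m <- evaluate_classifier(fits[[nm]]$params, species$test$X, species$test$y)
    data.frame(strategy = nm, bacc = m$bacc, mcc = m$mcc, auc = m$auc,
               auprc = m$auprc)
  })
  do.call(rbind, rows)
}

#' Cross-domain AUPRC increment matrix
#'
#' Entry (a, b) is `AUPRC(model_a on test_b) - AUPRC(model_b on test_b)`,
#' i.e. how much worse (negative) or better a foreign-domain model does on
#' domain b's test set than b's own model; the diagonal is 0 by definition.
#'
#' @param models Named list of `classifier_params`, one per domain.
#' @param testsets Named list of `list(X, y)` with the same names.
#' @return Square numeric matrix (train domain x test domain).
#' @export
cross_domain_matrix <- function(models, testsets) {
  stopifnot(identical(sort(names(models)), sort(names(testsets))))
  doms <- names(models)
  own <- vapply(doms, function(b) {
    auprc(testsets[[b]]$y, predict_classifier(models[[b]],
                                              testsets[[b]]$X)$prob)
  }, numeric(1L))
  m <- matrix(0, length(doms), length(doms), dimnames = list(doms, doms))
  for (a in doms) for (b in doms) {
    m[a, b] <- auprc(testsets[[b]]$y,
                     predict_classifier(models[[a]], testsets[[b]]$X)$prob) -
      own[b]
  }
  m
}
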
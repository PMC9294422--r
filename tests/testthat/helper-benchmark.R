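# The default transfer benchmark is trained once per test session and the
# results shared between the training-module and acceptance tests.

.bench_cache <- new.env(parent = emptyenv())

# Desk-scale training configuration used for every benchmark run.
bench_cfg <- function(seed) {
  train_config(max_epochs = 40L, plateau_patience = 3L,
               early_stop_patience = 6L, seed = seed)
}

# Runs DT/SP/GM/TSTL on the smallest species domain (D) for `n_seeds` seeds
# plus a frozen-GRU fine-tune on the first seed; returns test AUPRCs.
benchmark_results <- function(n_seeds = 5L) {
  key <- paste0("res", n_seeds)
  if (!is.null(.bench_cache[[key]])) return(.bench_cache[[key]])
  rows <- list()
  frozen <- NULL
  for (s in seq_len(n_seeds)) {
    bench <- gen_transfer_benchmark(s)
    pre <- split_domain(bench$pretrain, seed = s + 100L)
    spD <- split_domain(bench$species$D, seed = s + 200L)
    init <- init_classifier(16L, seed = s)
    cfg <- bench_cfg(s + 300L)
    suppressMessages({
      sp <- run_strategy("SP", pre, spD, init, cfg)
      dt <- run_strategy("DT", pre, spD, init, cfg)
      gm <- run_strategy("GM", pre, spD, init, cfg)
      ts <- run_strategy("TSTL", pre, spD, init, cfg, base_params = sp$params)
    })
    if (s == 1L) {
      fcfg <- bench_cfg(s + 300L)
      fcfg$freeze_gru <- TRUE
      suppressMessages(
        fr <- run_strategy("TSTL", pre, spD, init, cfg, finetune_cfg = fcfg,
                           base_params = sp$params))
      frozen <- list(sp = sp$params, fine = fr$params)
    }
    ev <- function(fit) auprc(spD$test$y,
                              predict_classifier(fit$params, spD$test$X)$prob)
    rows[[s]] <- c(DT = ev(dt), SP = ev(sp), GM = ev(gm), TSTL = ev(ts))
  }
  out <- list(auprc = do.call(rbind, rows), frozen = frozen)
  .bench_cache[[key]] <- out
  out
}
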
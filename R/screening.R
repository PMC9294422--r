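# Probability calibration (temperature scaling) and genome-scale proteome
# screening with confidence-binned summaries.

#' Fit a probability calibration map
#'
#' Temperature scaling: a single parameter T > 0 rescales the model's
#' pre-sigmoid scores so that `plogis(score / T)` minimizes the validation
#' negative log-likelihood. Being strictly monotone it never changes the
#' model's ranking (AUC is preserved exactly); T = 1 is the identity on
#' probabilities. The 1-D search is over log T.
#'
#' @param scores Pre-sigmoid validation scores.
#' @param labels Binary validation labels (both classes required).
#' @param method `"temperature"` or `"identity"`.
#' @return List of class `calibration_map` with `method`, `temperature`,
#'   `nll_before`, `nll_after`.
#' @export
fit_calibration <- function(scores, labels,
                            method = c("temperature", "identity")) {
  method <- match.arg(method)
  if (length(unique(labels)) < 2L) {
    stop("calibration requires both classes in the validation set")
  }
  nll <- function(temp) weighted_bce(labels, stats::plogis(scores / temp))
  before <- nll(1)
  temperature <- 1
  if (method == "temperature") {
    opt <- stats::optimize(function(lt) nll(exp(lt)), c(log(1e-2), log(1e2)))
    temperature <- exp(opt$minimum)
  }
  structure(list(method = method, temperature = temperature,
                 nll_before = before, nll_after = nll(temperature)),
            class = "calibration_map")
}

#' Apply a calibration map to scores
#'
#' @param calib `calibration_map`.
#' @param scores Pre-sigmoid scores.
#' @return Calibrated probabilities in (0, 1).
#' @export
apply_calibration <- function(calib, scores) {
  stats::plogis(scores / calib$temperature)
}

#' Confidence-bin counts
#'
#' Counts of confidences strictly greater than each threshold (the ">50%"
#' ... ">90%" reading); counts are necessarily non-increasing in the
#' threshold.
#'
#' @param confidences Values in (0, 1).
#' @param thresholds Increasing thresholds.
#' @return Named integer vector, one count per threshold.
#' @export
summarize_bins <- function(confidences,
                           thresholds = c(0.5, 0.6, 0.7, 0.8, 0.9)) {
  counts <- vapply(thresholds, function(t) sum(confidences > t), integer(1L))
  names(counts) <- sprintf(">%d%%", round(100 * thresholds))
  counts
}

#' Genome-scale proteome screening
#'
#' Excludes proteins that appeared in the training data (by exact id or
#' exact sequence match), truncates the survivors to `max_len` residues
#' (N-terminal prefix), scores them with the model, calibrates the scores
#' into confidences, and summarizes the confidence bins. Deterministic in
#' eval mode; the per-protein table is sorted by id.
#'
#' @param records Proteome dataset data.frame (see [read_fasta()]).
#' @param params Trained `classifier_params`.
#' @param featurizer Function mapping a dataset data.frame to a feature
#'   matrix with ids as rownames.
#' @param calib `calibration_map` (identity map when NULL).
#' @param exclude_ids Training ids to drop.
#' @param exclude_sequences Training sequences to drop (exact match).
#' @param max_len Truncation length, default 6000.
#' @param thresholds Confidence-bin thresholds.
#' @return List of class `screen_result` with `per_protein` (id, confidence,
#'   truncated, excluded, reason) and `summary` (per-threshold counts over
#'   the retained proteins).
#' @export
screen_proteome <- function(records, params, featurizer, calib = NULL,
                            exclude_ids = character(),
                            exclude_sequences = character(),
                            max_len = 6000L,
                            thresholds = c(0.5, 0.6, 0.7, 0.8, 0.9)) {
  if (is.null(calib)) {
    calib <- structure(list(method = "identity", temperature = 1,
                            nll_before = NA_real_, nll_after = NA_real_),
                       class = "calibration_map")
  }
  excluded <- records$id %in% exclude_ids |
    records$sequence %in% exclude_sequences
  reason <- ifelse(excluded, "training overlap", "")
  message(sprintf("screening: %d protein(s), %d excluded as training overlap",
                  nrow(records), sum(excluded)))
  kept <- records[!excluded, , drop = FALSE]
  per <- data.frame(id = records$id, confidence = NA_real_,
                    truncated = FALSE, excluded = excluded, reason = reason,
                    stringsAsFactors = FALSE)
  if (nrow(kept) == 0L) {
    warning("no proteins survive exclusion; empty screening result")
    counts <- summarize_bins(numeric(0), thresholds)
  } else {
    over <- nchar(kept$sequence) > max_len
    kept <- suppressMessages(truncate_sequences(kept, max_len))
    if (any(over)) {
      message(sprintf("truncated %d over-length sequence(s) to %d residues",
                      sum(over), max_len))
    }
    X <- featurizer(kept)
    pred <- predict_classifier(params, X)
    conf <- apply_calibration(calib, pred$score)
    idx <- match(kept$id, per$id)
    per$confidence[idx] <- conf
    per$truncated[idx] <- over
    counts <- summarize_bins(conf, thresholds)
  }
  per <- per[order(per$id), , drop = FALSE]
  rownames(per) <- NULL
  structure(list(per_protein = per, summary = counts,
                 thresholds = thresholds, max_len = max_len),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat(sprintf("<screen_result> %d protein(s), %d excluded\n",
              nrow(x$per_protein), sum(x$per_protein$excluded)))
  print(x$summary)
  invisible(x)
}

#' Write screening outputs
#'
#' Emits the per-protein TSV (id, confidence, flags) and the
#' threshold-by-count summary TSV, both sorted and byte-for-byte
#' reproducible in eval mode.
#'
#' @param result `screen_result`.
#' @param per_protein_path,summary_path Output paths (NULL skips).
#' @export
write_screen_result <- function(result, per_protein_path = NULL,
                                summary_path = NULL) {
  if (!is.null(per_protein_path)) {
    utils::write.table(result$per_protein, per_protein_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if (!is.null(summary_path)) {
    df <- data.frame(confidence_level = names(result$summary),
                     count = as.integer(result$summary))
    utils::write.table(df, summary_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(result)
}
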
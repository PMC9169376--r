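#' Validation-protocol configuration
#'
#' The protocol draws `m` segments per class, runs stratified `k`-fold
#' cross-validation on the balanced subset, and repeats the whole draw `n`
#' times with fresh subsets, so performance is assessed over
#' `m * n * k` different random data-subset combinations. The defaults
#' (`m = 20`, `n = 100`, `k = 10`) give 20,000 combinations.
#'
#' @param m Segments picked per class each repetition (default 20).
#' @param n Number of repetitions (default 100).
#' @param k Number of stratified folds (default 10).
#' @param seed Master seed; repetition `r` uses its own derived substream.
#' @param wavelets Wavelet names to sweep in [run_wavelet_sweep()].
#' @return A `validation_config` object.
#' @export
validation_config <- function(m = 20L, n = 100L, k = 10L, seed = 1L,
                              wavelets = supported_wavelets()) {
  m <- as.integer(m); n <- as.integer(n); k <- as.integer(k)
  if (is.na(k) || k < 2L) stop("config error: k must be >= 2")
  if (is.na(m) || m < 1L) stop("config error: m must be >= 1")
  if (is.na(n) || n < 1L) stop("config error: n must be >= 1")
  if (m * length(state_labels()) < k) {
    stop("config error: m * number of classes must be >= k")
  }
  structure(list(m = m, n = n, k = k, seed = as.integer(seed),
                 wavelets = wavelets),
            class = "validation_config")
}

#' @rdname validation_config
#' @param cfg A `validation_config`.
#' @return `cv_combination_count()` returns `m * n * k`, the number of
#'   random data-subset combinations the protocol assesses.
#' @export
cv_combination_count <- function(cfg) {
  with(cfg, as.numeric(m) * n * k)
}

#' Draw a balanced subset of segments
#'
#' Samples exactly `m` segments per class without replacement, removing the
#' slight class-size discrepancy of a recorded session before
#' cross-validation.
#'
#' @param segments List of labeled `segment`s.
#' @param m Segments per class.
#' @param seed Integer seed.
#' @return Sub-list of `segments` with `m` entries per class, in class-code
#'   order.
#' @export
pick_balanced_subset <- function(segments, m, seed = 1L) {
  labs <- vapply(segments, function(s) s$label, integer(1))
  set.seed(seed)
  segments[.balanced_idx(labs, m)]
}

# Balanced per-class sampling on label codes; uses the current RNG stream.
.balanced_idx <- function(labels, m) {
  counts <- table(labels)
  short <- counts[counts < m]
  if (length(short) > 0L) {
    stop("class ", state_name(as.integer(names(short)[1L])), " has only ",
         short[1L], " segments, need m = ", m)
  }
  unlist(lapply(sort(unique(labels)), function(code) {
    idx <- which(labels == code)
    idx[sample.int(length(idx), m)]
  }))
}

# Stratified fold assignment: within each class, shuffle and deal
# round-robin, so fold class-proportions match the data.
.stratified_folds <- function(labels, k) {
  folds <- integer(length(labels))
  for (code in unique(labels)) {
    idx <- which(labels == code)
    folds[idx[sample.int(length(idx))]] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

#' Normalized confusion matrix
#'
#' Entry `(i, j)` is the fraction of samples with true class `i` predicted
#' as class `j`; each row with support sums to 1. Rows for classes with no
#' true samples are all zero and listed in the `"zero_support"` attribute.
#'
#' @param true_labels,predicted_labels Equal-length integer state codes.
#' @param levels Class codes indexing the matrix (default all three states).
#' @return A square matrix with state names on both axes.
#' @examples
#' normalized_confusion(c(0, 0, 1, 2), c(0, 1, 1, 2))
#' @export
normalized_confusion <- function(true_labels, predicted_labels,
                                 levels = 0:2) {
  if (length(true_labels) == 0L) stop("empty label input")
  if (length(true_labels) != length(predicted_labels)) {
    stop("label sequences must have equal length")
  }
  counts <- table(factor(true_labels, levels = levels),
                  factor(predicted_labels, levels = levels))
  support <- rowSums(counts)
  norm <- counts / ifelse(support > 0, support, 1)
  out <- matrix(as.numeric(norm), nrow = length(levels),
                dimnames = list(true = state_name(levels),
                                predicted = state_name(levels)))
  attr(out, "zero_support") <- state_name(levels[support == 0])
  out
}

#' One-vs-rest ROC curve and AUC
#'
#' Thresholds the positive-class probability over its full range, tracing
#' the (FPR, TPR) staircase; ties in score are grouped. The AUC is the
#' trapezoidal area, which equals the Mann-Whitney U-statistic probability
#' (ties counted 1/2) that a positive outranks a negative.
#'
#' @param scores Numeric scores (positive-class probabilities).
#' @param truth Labels; `positive_class` marks the positives, everything
#'   else is negative.
#' @param positive_class Value of `truth` treated as positive.
#' @return List with `fpr`, `tpr` (curve vertices from (0,0) to (1,1)) and
#'   `auc`.
#' @examples
#' ovr_roc(c(0.9, 0.8, 0.3, 0.1), c(1, 1, 0, 0), positive_class = 1)$auc
#' @export
ovr_roc <- function(scores, truth, positive_class) {
  pos <- truth == positive_class
  P <- sum(pos); N <- sum(!pos)
  if (P == 0L || N == 0L) {
    stop("ROC undefined: need both positive and negative samples")
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- pos[ord]
  grp_end <- which(diff(s) != 0)          # last index of each tie group
  grp_end <- c(grp_end, length(s))
  tp <- cumsum(y)[grp_end]
  fp <- grp_end - tp
  fpr <- c(0, fp / N); tpr <- c(0, tp / P)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(fpr = fpr, tpr = tpr, auc = auc)
}

# Linear interpolation of a ROC staircase onto a fixed FPR grid; vertical
# segments (repeated fpr) collapse to their upper tpr.
.roc_on_grid <- function(roc, grid) {
  f <- roc$fpr; t <- roc$tpr
  keep <- rev(!duplicated(rev(f)))  # last (highest-tpr) point per fpr
  stats::approx(f[keep], t[keep], xout = grid, rule = 2)$y
}

#' Repeated stratified cross-validation of the DWT + forest pipeline
#'
#' The full validation protocol: for each of `n` repetitions a fresh
#' balanced subset (`m` segments per class) is split into `k` stratified
#' folds; each fold in turn is held out, a forest is trained on the
#' remaining folds' DWT features and scored on the held-out fold. Training
#' and test folds never overlap. Accuracies are aggregated over all
#' `n * k` fold evaluations, held-out predictions accumulate into a
#' normalized confusion matrix, and per-repetition pooled class
#' probabilities yield one-vs-rest ROC curves, vertically averaged on a
#' fixed 101-point FPR grid with a +/-1 sd band.
#'
#' @param segments List of labeled `segment`s (every class present with at
#'   least `m` members).
#' @param wavelet Wavelet name used for feature extraction.
#' @param forest_cfg A [forest_config()].
#' @param val_cfg A [validation_config()].
#' @param padding DWT padding mode.
#' @param keep_folds If `TRUE`, the report additionally records, for every
#'   repetition, the drawn subset indices and their fold assignment
#'   (`report$folds`), so train/test disjointness can be audited.
#' @return A `validation_report`: list with `wavelet`,
#'   `fold_accuracies` (`n x k` matrix), `mean_accuracy`, `sd_accuracy`
#'   (over all fold evaluations), `rep_mean_accuracies` and
#'   `sd_accuracy_over_reps` (the same spread measured across repetition
#'   means), normalized `confusion` (+ raw `confusion_counts`), `roc` (per
#'   one-vs-rest case: `fpr_grid`, `tpr_mean`, `tpr_sd`, `auc_mean`,
#'   `auc_sd`, per-repetition `aucs`), and `combination_count = m * n * k`.
#' @examples
#' \donttest{
#' rec <- simulate_session(list(list("Idle", 30), list("Stone", 30),
#'                              list("Tissue", 30)), seed = 1)
#' rep <- run_repeated_cv(segment_recording(rec), "haar",
#'                        val_cfg = validation_config(m = 10, n = 2, k = 5))
#' rep$mean_accuracy
#' }
#' @export
run_repeated_cv <- function(segments, wavelet = "dmey",
                            forest_cfg = forest_config(),
                            val_cfg = validation_config(),
                            padding = "symmetric", keep_folds = FALSE) {
  ft <- build_feature_table(segments, wavelet, padding = padding)
  X <- ft$features; y <- ft$labels
  classes <- sort(unique(y))
  m <- val_cfg$m; n_rep <- val_cfg$n; k <- val_cfg$k
  grid <- seq(0, 1, length.out = 101L)

  fold_acc <- matrix(NA_real_, n_rep, k)
  conf_counts <- matrix(0, 3L, 3L,
                        dimnames = list(true = state_name(0:2),
                                        predicted = state_name(0:2)))
  tpr_mat <- lapply(classes, function(c) matrix(NA_real_, n_rep, length(grid)))
  auc_mat <- matrix(NA_real_, n_rep, length(classes))
  names(tpr_mat) <- as.character(classes)
  fold_log <- if (keep_folds) vector("list", n_rep) else NULL

  for (r in seq_len(n_rep)) {
    set.seed((val_cfg$seed + r * 7919) %% 2147483647L)
    sub <- .balanced_idx(y, m)
    ys <- y[sub]
    folds <- .stratified_folds(ys, k)
    if (keep_folds) fold_log[[r]] <- list(subset = sub, fold = folds)
    truth <- integer(0)
    probs <- matrix(numeric(0), 0L, length(classes))
    for (f in seq_len(k)) {
      test <- sub[folds == f]; train <- sub[folds != f]
      fit <- train_forest(X[train, , drop = FALSE], y[train],
                          cfg = forest_cfg)
      p <- predict_proba(fit, X[test, , drop = FALSE])
      # align columns in case a class is absent from a training fold
      pfull <- matrix(0, nrow(p), length(classes),
                      dimnames = list(NULL, as.character(classes)))
      pfull[, colnames(p)] <- p
      pred <- classes[max.col(pfull, ties.method = "first")]
      fold_acc[r, f] <- mean(pred == y[test])
      for (i in seq_along(test)) {
        conf_counts[y[test[i]] + 1L, pred[i] + 1L] <-
          conf_counts[y[test[i]] + 1L, pred[i] + 1L] + 1
      }
      truth <- c(truth, y[test])
      probs <- rbind(probs, pfull)
    }
    for (ci in seq_along(classes)) {
      roc <- ovr_roc(probs[, ci], truth, positive_class = classes[ci])
      tpr_mat[[ci]][r, ] <- .roc_on_grid(roc, grid)
      auc_mat[r, ci] <- roc$auc
    }
  }

  support <- rowSums(conf_counts)
  confusion <- conf_counts / ifelse(support > 0, support, 1)
  attr(confusion, "zero_support") <- state_name(0:2)[support == 0]
  roc_cases <- lapply(seq_along(classes), function(ci) {
    list(positive = state_name(classes[ci]),
         fpr_grid = grid,
         tpr_mean = colMeans(tpr_mat[[ci]]),
         tpr_sd = apply(tpr_mat[[ci]], 2L, stats::sd),
         auc_mean = mean(auc_mat[, ci]),
         auc_sd = stats::sd(auc_mat[, ci]),
         aucs = auc_mat[, ci])
  })
  names(roc_cases) <- state_name(classes)
  rep_means <- rowMeans(fold_acc)

  structure(
    list(wavelet = wavelet, m = m, n = n_rep, k = k,
         combination_count = cv_combination_count(val_cfg),
         fold_accuracies = fold_acc,
         mean_accuracy = mean(fold_acc),
         sd_accuracy = stats::sd(as.numeric(fold_acc)),
         rep_mean_accuracies = rep_means,
         sd_accuracy_over_reps = stats::sd(rep_means),
         confusion = confusion, confusion_counts = conf_counts,
         roc = roc_cases, folds = fold_log),
    class = "validation_report"
  )
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> wavelet=%s m=%d n=%d k=%d (%s combinations)\n",
              x$wavelet, x$m, x$n, x$k,
              format(x$combination_count, big.mark = ",")))
  cat(sprintf("  accuracy: %.3f +/- %.3f (over %d fold evaluations; sd over repetition means %.3f)\n",
              x$mean_accuracy, x$sd_accuracy, length(x$fold_accuracies),
              x$sd_accuracy_over_reps))
  cat("  one-vs-rest AUC:",
      paste(sprintf("%s=%.3f", names(x$roc),
                    vapply(x$roc, `[[`, numeric(1), "auc_mean")),
            collapse = " "), "\n")
  cat("  normalized confusion (rows = true):\n")
  cm <- round(unclass(x$confusion), 3)
  attr(cm, "zero_support") <- NULL
  print(cm)
  invisible(x)
}

#' Sweep the wavelet families through the validation protocol
#'
#' Runs [run_repeated_cv()] once per wavelet and tabulates mean accuracy
#' and its spread, the per-family comparison that selects the best
#' performing wavelet.
#'
#' @inheritParams run_repeated_cv
#' @param wavelets Character vector of wavelet names.
#' @return List with `table` (data frame: wavelet, mean_accuracy,
#'   sd_accuracy) and `reports` (named list of `validation_report`s).
#' @export
run_wavelet_sweep <- function(segments, wavelets = supported_wavelets(),
                              forest_cfg = forest_config(),
                              val_cfg = validation_config(),
                              padding = "symmetric") {
  reports <- lapply(wavelets, function(wname) {
    run_repeated_cv(segments, wname, forest_cfg, val_cfg, padding)
  })
  names(reports) <- wavelets
  tab <- data.frame(
    wavelet = wavelets,
    mean_accuracy = vapply(reports, `[[`, numeric(1), "mean_accuracy"),
    sd_accuracy = vapply(reports, `[[`, numeric(1), "sd_accuracy"),
    row.names = NULL
  )
  list(table = tab, reports = reports)
}

#' Dummy-data null check
#'
#' Runs the identical DWT + forest + repeated-CV pipeline on uninformative
#' data: raw segments drawn i.i.d. uniform over a fixed amplitude range and
#' labeled evenly across the three states. An unbiased pipeline must score
#' at chance level -- mean accuracy near 1/3 and one-vs-rest AUCs near 0.5;
#' anything better would reveal a leak or bias in the procedure itself.
#'
#' @param val_cfg A [validation_config()].
#' @param forest_cfg A [forest_config()].
#' @param segment_shape List with `timestep` (segment length, default 50),
#'   `n_per_class` (dummy segments generated per class, default 60),
#'   `amplitude` (half-range of the uniform draw, default 1) and
#'   `sampling_rate_hz` (default 100).
#' @param seed Seed for the dummy-data draw.
#' @param wavelet Wavelet used for feature extraction (default `dmey`).
#' @return A `validation_report` with the same structure as a real-data run.
#' @export
run_dummy_null <- function(val_cfg = validation_config(),
                           forest_cfg = forest_config(),
                           segment_shape = list(), seed = 1L,
                           wavelet = "dmey") {
  shape <- utils::modifyList(
    list(timestep = 50L, n_per_class = 60L, amplitude = 1,
         sampling_rate_hz = 100),
    segment_shape
  )
  set.seed(seed)
  segments <- list()
  for (code in unname(state_labels())) {
    for (i in seq_len(shape$n_per_class)) {
      segments[[length(segments) + 1L]] <- structure(
        list(values = stats::runif(shape$timestep, -shape$amplitude,
                                   shape$amplitude),
             label = code,
             origin = list(recording = "<dummy>", start = NA_integer_),
             sampling_rate_hz = shape$sampling_rate_hz),
        class = "segment"
      )
    }
  }
  run_repeated_cv(segments, wavelet, forest_cfg, val_cfg)
}
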
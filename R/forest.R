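#' Random-forest configuration
#'
#' Mirrors the default hyperparameters of the standard ensemble-tree
#' implementation used in this field: 100 trees, bootstrap resampling,
#' Gini impurity, a random subset of `ceiling(sqrt(d))` features evaluated
#' at each split, trees grown to purity.
#'
#' @param n_trees Number of trees (default 100).
#' @param max_features Per-split feature subset rule; only `"sqrt"` is
#'   supported (`ceiling(sqrt(d))`, clamped to at least 1).
#' @param split_criterion Only `"gini"` is supported.
#' @param bootstrap If `TRUE` (default) each tree trains on a bootstrap
#'   resample of the full training set; if `FALSE`, on the full set itself.
#' @param min_samples_split Minimum samples to split a node (default 2,
#'   i.e. grow to purity).
#' @param max_depth Maximum tree depth; `NULL` (default) for unlimited.
#' @param seed Integer seed making training deterministic.
#' @return A `forest_config` object.
#' @export
forest_config <- function(n_trees = 100L, max_features = "sqrt",
                          split_criterion = "gini", bootstrap = TRUE,
                          min_samples_split = 2L, max_depth = NULL,
                          seed = 1L) {
  max_features <- match.arg(max_features, "sqrt")
  split_criterion <- match.arg(split_criterion, "gini")
  n_trees <- as.integer(n_trees)
  if (is.na(n_trees) || n_trees < 1L) stop("n_trees must be >= 1")
  structure(list(n_trees = n_trees, max_features = max_features,
                 split_criterion = split_criterion, bootstrap = bootstrap,
                 min_samples_split = as.integer(min_samples_split),
                 max_depth = max_depth, seed = as.integer(seed)),
            class = "forest_config")
}

#' Train a random-forest state classifier
#'
#' Fits an ensemble of axis-aligned decision trees on DWT feature vectors
#' (or any numeric feature matrix). The forest itself is fitted with the
#' \pkg{randomForest} package (Breiman-Cutler trees, Gini splits); this
#' wrapper pins the contract the rest of the pipeline relies on: classes
#' ordered by state code, `ceiling(sqrt(d))` features per split, trees grown
#' to purity, and full determinism given `(data, seed)`.
#'
#' @param features A `feature_table` from [build_feature_table()], or a
#'   numeric matrix (then `labels` must be given).
#' @param labels Integer state codes, one per row (ignored when `features`
#'   is a `feature_table`).
#' @param cfg A [forest_config()].
#' @return A `trained_forest`: list with the fitted ensemble, `classes`
#'   (sorted codes seen in training), `n_features`, `config`, and
#'   `feature_meta` (wavelet/padding/timestep when trained from a
#'   `feature_table`).
#' @examples
#' x <- matrix(rnorm(60), 20, 3)
#' y <- rep(0:1, each = 10)
#' fit <- train_forest(x, y, forest_config(n_trees = 25, seed = 1))
#' predict_forest(fit, x)[1:5]
#' @export
train_forest <- function(features, labels = NULL, cfg = forest_config()) {
  feature_meta <- NULL
  if (inherits(features, "feature_table")) {
    feature_meta <- features[c("wavelet", "padding", "timestep")]
    labels <- features$labels
    features <- features$features
  }
  features <- as.matrix(features)
  if (nrow(features) == 0L) stop("empty training set")
  if (length(labels) != nrow(features)) {
    stop("labels must have one entry per feature row")
  }
  check_label_codes(labels)
  classes <- sort(unique(as.integer(labels)))
  d <- ncol(features)
  mtry <- max(1L, min(d, as.integer(ceiling(sqrt(d)))))

  if (length(classes) == 1L) {
    # degenerate but legal: a single-state training set yields a constant
    # classifier (randomForest itself needs >= 2 classes)
    rf <- NULL
  } else {
    y <- factor(as.integer(labels), levels = classes)
    set.seed(cfg$seed)
    rf <- randomForest::randomForest(
      x = features, y = y,
      ntree = cfg$n_trees, mtry = mtry,
      replace = cfg$bootstrap, sampsize = nrow(features),
      nodesize = max(1L, cfg$min_samples_split - 1L),
      maxnodes = if (is.null(cfg$max_depth)) NULL else 2L^cfg$max_depth
    )
  }
  structure(list(rf = rf, classes = classes, n_features = d,
                 config = cfg, feature_meta = feature_meta),
            class = "trained_forest")
}

#' Per-class vote probabilities
#'
#' Averages the per-tree leaf class votes into a probability row per input;
#' rows are normalized to sum to exactly 1. Columns follow `model$classes`
#' (ascending state code).
#'
#' @param model A `trained_forest`.
#' @param features Numeric matrix (or `feature_table`) with the training
#'   feature dimension.
#' @return Numeric matrix, one row per input, one column per trained class
#'   (named by state code).
#' @export
predict_proba <- function(model, features) {
  stopifnot(inherits(model, "trained_forest"))
  if (inherits(features, "feature_table")) features <- features$features
  features <- as.matrix(features)
  if (ncol(features) != model$n_features) {
    stop("feature dimension mismatch: model expects ", model$n_features,
         " features, got ", ncol(features))
  }
  if (is.null(model$rf)) {
    p <- matrix(1, nrow(features), 1L)
  } else {
    colnames(features) <- rownames(model$rf$importance)
    p <- stats::predict(model$rf, features, type = "prob")
    p <- p[, as.character(model$classes), drop = FALSE]
  }
  p <- p / rowSums(p)
  dimnames(p) <- list(NULL, as.character(model$classes))
  p
}

#' @rdname predict_proba
#' @return `predict_forest()` returns the integer state code per row, the
#'   argmax of the probability row; ties resolve to the lowest class code.
#' @export
predict_forest <- function(model, features) {
  p <- predict_proba(model, features)
  model$classes[max.col(p, ties.method = "first")]
}
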
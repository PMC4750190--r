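# Random-forest discrimination of boundary regions from a control class,
# with an SVM cross-check, following the usual genomics workflow: 70/30
# train/test split, out-of-bag tuning of the per-split feature sample m,
# unpruned trees, majority vote, and permutation (mean-decrease-accuracy)
# importances.

#' Train/test split specification
#' @param train_fraction fraction of rows used for training (default 0.70).
#' @param seed RNG seed governing the split and all downstream randomness.
#' @export
split_spec <- function(train_fraction = 0.70, seed = 1L) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  list(train_fraction = train_fraction, seed = as.integer(seed))
}

#' Random-forest specification
#' @param n_trees trees per forest (default 500).
#' @param m features sampled at each split; `NULL` = one third of the
#'   feature count (the classical regression default, which the tuning grid
#'   is centred on).
#' @export
forest_spec <- function(n_trees = 500L, m = NULL) {
  list(n_trees = as.integer(n_trees), m = m)
}

as_xy <- function(features) {
  stopifnot(inherits(features, "feature_matrix"))
  list(x = features$x, y = droplevels(features$labels))
}

#' Tune m by out-of-bag error
#'
#' Fits one forest per candidate m on the full data and returns the candidate
#' with the lowest out-of-bag error; ties break toward smaller m.
#'
#' @param features a `feature_matrix` with two classes.
#' @param spec a [forest_spec()].
#' @param grid candidate m values; default is a multiplier grid around
#'   one third of the feature count.
#' @param seed RNG seed.
#' @return the selected m; attribute `oob` holds the per-candidate errors.
#' @export
tune_m <- function(features, spec = forest_spec(), grid = NULL, seed = 1L) {
  d <- as_xy(features)
  if (nlevels(d$y) < 2L) stopf("tuning requires two classes, got %d", nlevels(d$y))
  nf <- ncol(d$x)
  if (is.null(grid))
    grid <- unique(pmin(nf, pmax(1L, round(nf / 3 * c(0.25, 0.5, 1, 2, 3)))))
  grid <- sort(unique(as.integer(grid)))
  oob <- vapply(seq_along(grid), function(i) {
    with_seed(substream_seed(seed, i), {
      rf <- randomForest::randomForest(d$x, d$y, ntree = spec$n_trees,
                                       mtry = grid[i])
      rf$err.rate[spec$n_trees, "OOB"]
    })
  }, numeric(1))
  best <- grid[which.min(oob)]   # which.min takes the first (smallest m) on ties
  attr(best, "oob") <- stats::setNames(oob, grid)
  best
}

roc_points <- function(score, is_pos) {
  o <- order(score, decreasing = TRUE)
  score <- score[o]; is_pos <- is_pos[o]
  # pool tied scores so the ROC steps once per distinct threshold
  tp <- cumsum(is_pos); fp <- cumsum(!is_pos)
  last <- !duplicated(score, fromLast = TRUE)
  data.frame(threshold = c(Inf, score[last]),
             tpr = c(0, tp[last]) / sum(is_pos),
             fpr = c(0, fp[last]) / sum(!is_pos))
}

trapezoid_auc <- function(roc) {
  sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) + utils::tail(roc$tpr, -1)) / 2)
}

# Operating point maximizing the F-measure over vote-fraction thresholds.
best_f_point <- function(score, is_pos) {
  thr <- sort(unique(score))
  best <- list(f = -1)
  for (t in thr) {
    pred <- score >= t
    tp <- sum(pred & is_pos); fp <- sum(pred & !is_pos)
    fn <- sum(!pred & is_pos); tn <- sum(!pred & !is_pos)
    prec <- if (tp + fp) tp / (tp + fp) else 0
    rec <- if (tp + fn) tp / (tp + fn) else 0
    f <- if (prec + rec) 2 * prec * rec / (prec + rec) else 0
    if (f > best$f)
      best <- list(f = f, threshold = t, tp = tp, fp = fp, fn = fn, tn = tn,
                   precision = prec, recall = rec)
  }
  best
}

build_report <- function(score, is_pos, importance = NULL, extra = list()) {
  roc <- roc_points(score, is_pos)
  op <- best_f_point(score, is_pos)
  rep <- c(list(sensitivity = op$recall,
                specificity = op$tn / (op$tn + op$fp),
                precision = op$precision,
                f_measure = op$f,
                auc = trapezoid_auc(roc),
                threshold = op$threshold,
                confusion = c(tp = op$tp, fp = op$fp, fn = op$fn, tn = op$tn),
                roc = roc,
                importance = importance),
           extra)
  class(rep) <- "classifier_report"
  rep
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf("classifier report (%s): sens %.3f spec %.3f F %.3f AUC %.3f (n_test=%d)\n",
              x$method %||% "?", x$sensitivity, x$specificity, x$f_measure,
              x$auc, sum(x$confusion)))
  invisible(x)
}

#' Random-forest discrimination with held-out evaluation
#'
#' Fits an unpruned majority-vote forest on a random 70/30 split and reports
#' held-out sensitivity, specificity and F-measure at the F-optimal
#' vote-fraction threshold, the trapezoidal ROC AUC, and mean-decrease-accuracy
#' importances.  The F-optimal operating point is chosen on the test set,
#' which is optimistic by construction; this is recorded in the report.
#'
#' @param features `feature_matrix` with exactly two classes.
#' @param split a [split_spec()].
#' @param spec a [forest_spec()].
#' @param positive name of the positive class (default `"boundary"` when
#'   present, otherwise the first level).
#' @return a `classifier_report`.
#' @export
train_evaluate <- function(features, split = split_spec(),
                           spec = forest_spec(), positive = NULL) {
  d <- as_xy(features)
  if (nlevels(d$y) != 2L)
    stopf("need exactly two classes, got: %s", paste(levels(d$y), collapse = ", "))
  positive <- positive %||% if ("boundary" %in% levels(d$y)) "boundary"
                            else levels(d$y)[1]
  n <- nrow(d$x)
  idx <- with_seed(substream_seed(split$seed, 1),
                   sample.int(n, round(split$train_fraction * n)))
  ytr <- d$y[idx]
  if (nlevels(droplevels(ytr)) < 2L) stopf("a class is absent from the train split")
  m <- spec$m %||% max(1L, floor(ncol(d$x) / 3))
  rf <- with_seed(substream_seed(split$seed, 2),
                  randomForest::randomForest(d$x[idx, , drop = FALSE], ytr,
                                             ntree = spec$n_trees, mtry = m,
                                             importance = TRUE))
  votes <- predict(rf, d$x[-idx, , drop = FALSE], type = "prob")[, positive]
  is_pos <- d$y[-idx] == positive
  imp <- rf$importance[, "MeanDecreaseAccuracy"]
  build_report(votes, is_pos, importance = imp,
               extra = list(method = "random_forest", positive = positive,
                            m = m, n_trees = spec$n_trees,
                            n_train = length(idx), n_test = n - length(idx),
                            operating_point_note = "F-optimal threshold chosen on held-out votes"))
}

#' SVM replication of the discrimination task (10-fold cross-validation)
#'
#' @param features `feature_matrix` with two classes.
#' @param split a [split_spec()]; only its seed is used (folds replace the
#'   70/30 split).
#' @param folds number of cross-validation folds (default 10).
#' @param positive positive class as in [train_evaluate()].
#' @return a `classifier_report` (no importances).
#' @export
train_evaluate_margin <- function(features, split = split_spec(), folds = 10L,
                                  positive = NULL) {
  d <- as_xy(features)
  if (nlevels(d$y) != 2L) stopf("need exactly two classes")
  positive <- positive %||% if ("boundary" %in% levels(d$y)) "boundary"
                            else levels(d$y)[1]
  n <- nrow(d$x)
  fold <- with_seed(substream_seed(split$seed, 3),
                    sample(rep_len(seq_len(folds), n)))
  score <- numeric(n)
  for (f in seq_len(folds)) {
    te <- which(fold == f); tr <- which(fold != f)
    if (nlevels(droplevels(d$y[tr])) < 2L) stopf("a class is absent from a training fold")
    fit <- with_seed(substream_seed(split$seed, 100 + f),
                     e1071::svm(d$x[tr, , drop = FALSE], d$y[tr],
                                kernel = "radial", probability = TRUE))
    pr <- attr(predict(fit, d$x[te, , drop = FALSE], probability = TRUE),
               "probabilities")[, positive]
    score[te] <- pr
  }
  build_report(score, d$y == positive,
               extra = list(method = "svm_10fold", positive = positive,
                            folds = folds, n_test = n))
}

#' Rank features by mean decrease accuracy
#' @param report a `classifier_report` with importances.
#' @param k number of top features; ties break lexicographically by id.
#' @return character vector of feature ids, most important first.
#' @export
rank_importances <- function(report, k) {
  imp <- report$importance
  if (is.null(imp)) stopf("report carries no importances")
  if (k > length(imp)) stopf("k = %d exceeds the %d features", k, length(imp))
  ord <- order(-imp, names(imp))
  names(imp)[ord][seq_len(k)]
}
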
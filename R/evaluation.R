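#' Map valence/arousal ratings to class labels
#'
#' Quadrant scheme: both ratings thresholded at `threshold` (default 5, with
#' the boundary counted as High), giving classes 1 = HAHV, 2 = HALV,
#' 3 = LAHV, 4 = LALV (High/Low Arousal x High/Low Valence). Binary scheme:
#' valence at or above the threshold is the positive class `+1`, below is
#' `-1`.
#'
#' @param ratings matrix/data frame with columns (valence, arousal); a
#'   numeric vector of valence is accepted for the binary scheme.
#' @param scheme `"quadrant"` or `"binary"`.
#' @param threshold rating threshold.
#' @return integer label vector.
#' @examples
#' assign_labels(cbind(5, 5))          # 1 (HAHV)
#' assign_labels(cbind(9, 4.9))        # 3 (LAHV)
#' @export
assign_labels <- function(ratings, scheme = c("quadrant", "binary"),
                          threshold = 5) {
  scheme <- match.arg(scheme)
  if (is.null(dim(ratings))) ratings <- cbind(ratings, NA_real_)
  ratings <- as.matrix(ratings)
  val <- ratings[, 1]
  if (scheme == "binary") {
    return(ifelse(val >= threshold, 1L, -1L))
  }
  if (ncol(ratings) < 2 || anyNA(ratings[, 2])) {
    stop("quadrant labeling needs both valence and arousal ratings")
  }
  aro <- ratings[, 2]
  ifelse(aro >= threshold,
         ifelse(val >= threshold, 1L, 2L),
         ifelse(val >= threshold, 3L, 4L))
}

#' Train a linear SVM / predict labels
#'
#' Thin wrappers around the libsvm binding: soft-margin linear kernel with
#' cost 1 (the toolbox default), one-vs-one multiclass, no internal scaling
#' (normalization is handled explicitly by [normalize_features()] on training
#' folds).
#'
#' @param features trials x features numeric matrix.
#' @param labels training class labels (>= 2 classes).
#' @return `train_classifier`: a fitted model; `predict_labels`: a vector of
#'   predicted labels with the input label type.
#' @export
train_classifier <- function(features, labels) {
  y <- factor(labels)
  if (nlevels(y) < 2) stop("training labels contain a single class")
  fit <- e1071::svm(as.matrix(features), y, kernel = "linear", cost = 1,
                    scale = FALSE, type = "C-classification")
  fit$label_type <- if (is.numeric(labels)) "integer" else "factor"
  fit
}

#' @rdname train_classifier
#' @param model a model from [train_classifier()].
#' @export
predict_labels <- function(model, features) {
  p <- stats::predict(model, as.matrix(features))
  if (identical(model$label_type, "integer")) {
    as.integer(as.character(p))
  } else p
}

#' Selector specification for the evaluation harness
#'
#' @param method `"mldw"` (PSO with a w1-w6 schedule), `"ldw"` (PSO, w0),
#'   `"constant"` (PSO, constant inertia), `"relief"`, or `"none"`.
#' @param strategy MLDW strategy name for `method = "mldw"`.
#' @param tmax PSO iteration budget.
#' @param n_particles swarm size.
#' @param inner_folds PSO fitness folds.
#' @param keep_fraction Relief keep fraction.
#' @param theta PSO selection threshold.
#' @return list of class `selector_spec`.
#' @export
selector_spec <- function(method = c("mldw", "ldw", "constant", "relief", "none"),
                          strategy = "w6", tmax = 50, n_particles = 20,
                          inner_folds = 3, keep_fraction = 0.5, theta = 0.8) {
  method <- match.arg(method)
  structure(list(method = method, strategy = strategy, tmax = tmax,
                 n_particles = n_particles, inner_folds = inner_folds,
                 keep_fraction = keep_fraction, theta = theta),
            class = "selector_spec")
}

selector_schedule <- function(spec) {
  switch(spec$method,
         mldw = mldw_strategy(spec$strategy, tmax = spec$tmax),
         ldw = mldw_strategy("w0", tmax = spec$tmax),
         constant = inertia_schedule("constant", tmax = spec$tmax),
         NULL)
}

run_selector <- function(spec, features, labels, seed) {
  switch(spec$method,
    none = rep(TRUE, ncol(features)),
    relief = relief_select(features, labels, spec$keep_fraction),
    {
      res <- select_features(features, labels,
                             schedule = selector_schedule(spec),
                             n_particles = spec$n_particles,
                             theta = spec$theta,
                             inner_folds = spec$inner_folds, seed = seed)
      mask <- res$mask
      attr(mask, "result") <- res
      mask
    })
}

#' Nested cross-validation with in-fold feature selection
#'
#' Outer stratified k-fold protocol: for each fold, normalization statistics
#' are fitted on the training folds only, the selector is run on the
#' (normalized) training folds only, a linear SVM is trained on the masked
#' training data, and accuracy is measured on the masked held-out fold. The
#' mask and the normalization never see the test fold, so the reported
#' accuracy is leak-free.
#'
#' @param x a trials x features numeric matrix, or a [trial_set()] (features
#'   are then extracted with [extract_features()] defaults).
#' @param labels per-trial labels; taken from the trial set when omitted.
#' @param selector a [selector_spec()].
#' @param k number of outer folds.
#' @param seed RNG seed controlling fold assignment and selector seeds.
#' @return list of class `eval_report`: per-fold accuracies, mean and sd
#'   accuracy, per-fold masks, pooled confusion matrix, selector echo, seed.
#' @export
nested_crossval <- function(x, labels = NULL, selector = selector_spec("mldw"),
                            k = 5, seed = 1) {
  if (inherits(x, "trial_set")) {
    if (is.null(labels)) labels <- x$labels
    x <- extract_features(x)
  }
  x <- as.matrix(x)
  stopifnot(length(labels) == nrow(x))
  fold <- with_seed(seed, stratified_folds(labels, k))
  accs <- numeric(k)
  masks <- vector("list", k)
  lev <- sort(unique(labels))
  conf <- matrix(0L, length(lev), length(lev),
                 dimnames = list(truth = lev, pred = lev))
  for (f in seq_len(k)) {
    tr <- fold != f
    nz <- normalize_features(x[tr, , drop = FALSE])
    xte <- normalize_features(x[!tr, , drop = FALSE], nz$stats)$features
    mask <- run_selector(selector, nz$features, labels[tr], seed + f)
    masks[[f]] <- as.logical(mask)
    model <- train_classifier(nz$features[, masks[[f]], drop = FALSE],
                              labels[tr])
    pred <- predict_labels(model, xte[, masks[[f]], drop = FALSE])
    truth <- labels[!tr]
    accs[f] <- mean(pred == truth)
    for (i in seq_along(truth)) {
      conf[as.character(truth[i]), as.character(pred[i])] <-
        conf[as.character(truth[i]), as.character(pred[i])] + 1L
    }
  }
  structure(list(fold_accuracy = accs, mean_accuracy = mean(accs),
                 sd_accuracy = stats::sd(accs), masks = masks,
                 confusion = conf, fold_assignment = fold,
                 selector = selector, k = k, seed = seed),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %d-fold accuracy %.2f%% +/- %.2f%% (selector: %s)\n",
              x$k, 100 * x$mean_accuracy, 100 * x$sd_accuracy,
              x$selector$method))
  cat("  per fold:", paste(sprintf("%.2f", 100 * x$fold_accuracy),
                           collapse = " "), "\n")
  invisible(x)
}

#' Compare inertia strategies across iteration budgets
#'
#' For each strategy, runs the nested protocol once per seed with the largest
#' requested budget and scores the best-so-far mask at each intermediate
#' budget (taken from the selection trace), yielding a strategies x budgets
#' accuracy table.
#'
#' @param x feature matrix or [trial_set()] (see [nested_crossval()]).
#' @param labels per-trial labels.
#' @param strategies character vector of strategy names (`"w0"`-`"w6"`).
#' @param budgets iteration budgets at which to tabulate accuracy.
#' @param k outer folds.
#' @param seeds integer vector of seeds to average over.
#' @param n_particles swarm size.
#' @param inner_folds PSO fitness folds.
#' @return data frame with columns `strategy`, `budget`, `mean_accuracy`,
#'   `sd_accuracy` (sd across folds x seeds).
#' @export
compare_selectors <- function(x, labels = NULL,
                              strategies = c("w0", "w2", "w6"),
                              budgets = c(10, 30, 50), k = 5, seeds = 1,
                              n_particles = 20, inner_folds = 3) {
  if (inherits(x, "trial_set")) {
    if (is.null(labels)) labels <- x$labels
    x <- extract_features(x)
  }
  x <- as.matrix(x)
  stopifnot(length(strategies) >= 1, length(budgets) >= 1)
  tmax <- max(budgets)
  rows <- list()
  for (st in strategies) {
    acc <- matrix(NA_real_, 0, length(budgets))
    for (seed in seeds) {
      fold <- with_seed(seed, stratified_folds(labels, k))
      for (f in seq_len(k)) {
        tr <- fold != f
        nz <- normalize_features(x[tr, , drop = FALSE])
        xte <- normalize_features(x[!tr, , drop = FALSE], nz$stats)$features
        res <- select_features(nz$features, labels[tr],
                               schedule = mldw_strategy(st, tmax = tmax),
                               n_particles = n_particles,
                               inner_folds = inner_folds, seed = seed + f)
        a <- vapply(budgets, function(b) {
          mask <- decode_mask(res$gbest_trace[b, ], res$theta)
          model <- train_classifier(nz$features[, mask, drop = FALSE],
                                    labels[tr])
          mean(predict_labels(model, xte[, mask, drop = FALSE]) == labels[!tr])
        }, numeric(1))
        acc <- rbind(acc, a)
      }
    }
    rows[[st]] <- data.frame(strategy = st, budget = budgets,
                             mean_accuracy = colMeans(acc),
                             sd_accuracy = apply(acc, 2, stats::sd))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
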
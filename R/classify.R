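# Feature normalization, F-score ranking, RBF-SVM with grid search, and the
# two train/test split protocols.

#' Normalize features with training-set statistics
#'
#' Mean-centers and variance-scales every feature using statistics computed
#' from the training rows only; test rows are transformed with the same
#' statistics. Zero-variance features pass through with scale 1.
#'
#' @param train numeric matrix/data.frame of training rows.
#' @param test optional matrix of test rows (same columns).
#' @return List with \code{train}, \code{test} (or NULL), \code{center},
#'   \code{scale}.
#' @export
normalize_features <- function(train, test = NULL) {
  train <- as.matrix(train)
  if (!nrow(train)) stop("empty training set")
  ctr <- colMeans(train)
  scl <- apply(train, 2, stats::sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  tr <- sweep(sweep(train, 2, ctr), 2, scl, "/")
  te <- NULL
  if (!is.null(test)) {
    test <- as.matrix(test)
    te <- sweep(sweep(test, 2, ctr), 2, scl, "/")
  }
  list(train = tr, test = te, center = ctr, scale = scl)
}

#' Rank features by multi-class F-score
#'
#' Discrimination power of each feature: the ratio of between-class scatter
#' to pooled within-class variance, F = sum_c (mean_c - mean)^2 / sum_c
#' var_c. Perfect separation with zero within-class variance yields the
#' +Inf sentinel; identical class means yield 0.
#'
#' @param rows numeric matrix/data.frame (rows = cells, cols = features).
#' @param labels class label per row (>= 2 classes present).
#' @return Object of class \code{feature_ranking}: data.frame with
#'   \code{feature}, \code{fscore}, \code{rank}, ordered by descending score.
#' @export
fscore_rank <- function(rows, labels) {
  rows <- as.matrix(rows)
  labels <- as.character(labels)
  cls <- unique(labels)
  if (length(cls) < 2) stop("F-score needs at least two classes")
  scores <- apply(rows, 2, function(x) {
    num <- 0; den <- 0
    gm <- mean(x)
    for (c in cls) {
      xc <- x[labels == c]
      num <- num + (mean(xc) - gm)^2
      den <- den + (if (length(xc) > 1) stats::var(xc) else 0)
    }
    if (den == 0) return(if (num > 0) Inf else 0)
    num / den
  })
  out <- data.frame(feature = colnames(rows), fscore = unname(scores),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$fscore, out$feature), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("feature_ranking", class(out))
  out
}

#' Default hyperparameter grid for the RBF-SVM
#'
#' The canonical coarse grid: C over 2^-5..2^15 and gamma over 2^-15..2^3,
#' both in powers of 4.
#'
#' @return List with numeric vectors \code{C} and \code{gamma}.
#' @export
svm_grid <- function() {
  list(C = 2^seq(-5, 15, by = 2), gamma = 2^seq(-15, 3, by = 2))
}

#' Fit the RBF-kernel SVM cell classifier
#'
#' Normalizes features on the training rows, selects (C, gamma) by
#' stratified k-fold cross-validated accuracy over the grid (ties broken
#' toward smaller C, then smaller gamma), and refits on all training rows.
#' Multi-class handling is one-vs-one voting. If some class has fewer
#' members than \code{folds}, the fold count is reduced with a warning.
#'
#' @param x numeric matrix/data.frame of training feature rows.
#' @param y class label per row (>= 2 classes).
#' @param grid hyperparameter grid, see \code{\link{svm_grid}}.
#' @param folds cross-validation folds (default 5).
#' @param features optional character vector restricting/ordering the
#'   feature columns used.
#' @param seed seed for the fold assignment.
#' @return Object of class \code{myo_svm} with the fitted decision function,
#'   normalization statistics, selected features, C, gamma and CV accuracy.
#' @export
svm_classifier <- function(x, y, grid = svm_grid(), folds = 5,
                           features = NULL, seed = 1) {
  x <- as.matrix(x)
  if (!is.null(features)) {
    miss <- setdiff(features, colnames(x))
    if (length(miss)) stop("missing feature column(s): ",
                           paste(miss, collapse = ", "))
    x <- x[, features, drop = FALSE]
  }
  y <- factor(as.character(y))
  if (nlevels(y) < 2) stop("need at least two classes")
  if (!length(grid$C) || !length(grid$gamma)) stop("empty hyperparameter grid")
  min_class <- min(table(y))
  if (min_class < folds) {
    warning("smallest class has ", min_class, " rows; reducing folds")
    folds <- max(2, min_class)
  }
  nz <- normalize_features(x)
  xt <- nz$train
  fold_id <- stratified_folds(y, folds, seed)
  combos <- expand.grid(C = grid$C, gamma = grid$gamma)
  cv_acc <- numeric(nrow(combos))
  for (g in seq_len(nrow(combos))) {
    correct <- 0
    for (f in seq_len(folds)) {
      tr <- fold_id != f
      fit <- e1071::svm(xt[tr, , drop = FALSE], y[tr], kernel = "radial",
                        cost = combos$C[g], gamma = combos$gamma[g],
                        scale = FALSE)
      pred <- stats::predict(fit, xt[!tr, , drop = FALSE])
      correct <- correct + sum(pred == y[!tr])
    }
    cv_acc[g] <- correct / length(y)
  }
  best <- order(-cv_acc, combos$C, combos$gamma)[1]
  fit <- e1071::svm(xt, y, kernel = "radial", cost = combos$C[best],
                    gamma = combos$gamma[best], scale = FALSE)
  structure(list(fit = fit, center = nz$center, scale = nz$scale,
                 features = colnames(x), C = combos$C[best],
                 gamma = combos$gamma[best], cv_accuracy = cv_acc[best],
                 folds = folds, levels = levels(y), seed = seed),
            class = "myo_svm")
}

stratified_folds <- function(y, folds, seed) {
  fold_id <- integer(length(y))
  with_seed(seed, {
    for (cl in levels(y)) {
      w <- sample(which(y == cl))
      fold_id[w] <- rep_len(seq_len(folds), length(w))
    }
  })
  fold_id
}

#' @export
print.myo_svm <- function(x, ...) {
  cat(sprintf(
    "RBF-SVM cell classifier: %d features, C = %g, gamma = %g (%d-fold CV accuracy %.3f)\nClasses: %s\n",
    length(x$features), x$C, x$gamma, x$folds, x$cv_accuracy,
    paste(x$levels, collapse = ", ")))
  invisible(x)
}

#' @export
summary.myo_svm <- function(object, ...) {
  print(object)
  cat("Support vectors:", nrow(object$fit$SV), "\n")
  invisible(object)
}

#' Predict histotype labels for feature rows
#'
#' @param object fitted \code{myo_svm}.
#' @param newdata matrix/data.frame containing all selected feature columns.
#' @param ... unused.
#' @return Character vector of predicted class labels.
#' @export
predict.myo_svm <- function(object, newdata, ...) {
  newdata <- as.data.frame(newdata)
  miss <- setdiff(object$features, names(newdata))
  if (length(miss))
    stop("missing feature column(s): ", paste(miss, collapse = ", "))
  newdata <- as.matrix(newdata[, object$features, drop = FALSE])
  xn <- sweep(sweep(newdata, 2, object$center), 2, object$scale, "/")
  as.character(stats::predict(object$fit, xn))
}

#' Build train/test splits under the two protocols
#'
#' \code{random_cell_70_30}: per repetition, a class-stratified random split
#' of cells into 70\% training and 30\% test rows. \code{leave_one_case_out_21_1}:
#' per repetition one whole case becomes the test set; test cases are drawn
#' without replacement across repetitions while possible.
#'
#' @param data data.frame with a \code{histotype} column and, in case mode,
#'   a \code{case_id} column.
#' @param mode split protocol.
#' @param repetitions number of repetitions (default 5 for the cell split,
#'   10 for the case split).
#' @param seed seed.
#' @return List of \code{repetitions} elements, each a list with integer row
#'   indices \code{train} and \code{test} (disjoint).
#' @export
make_splits <- function(data, mode = c("random_cell_70_30",
                                       "leave_one_case_out_21_1"),
                        repetitions = NULL, seed = 1) {
  mode <- match.arg(mode)
  if (!nrow(data)) stop("empty dataset")
  if (is.null(repetitions))
    repetitions <- if (mode == "random_cell_70_30") 5 else 10
  splits <- vector("list", repetitions)
  if (mode == "random_cell_70_30") {
    y <- as.character(data$histotype)
    n <- nrow(data)
    target <- round(0.7 * n)
    with_seed(seed, {
      for (r in seq_len(repetitions)) {
        tr <- integer(0)
        # largest-remainder allocation of the 70% across classes
        tab <- table(y)
        alloc <- floor(0.7 * tab)
        rem <- target - sum(alloc)
        if (rem > 0) {
          fr <- 0.7 * tab - alloc
          add <- names(sort(fr, decreasing = TRUE))[seq_len(rem)]
          alloc[add] <- alloc[add] + 1
        }
        for (cl in names(tab)) {
          w <- which(y == cl)
          tr <- c(tr, sample(w, alloc[[cl]]))
        }
        splits[[r]] <- list(train = sort(tr),
                            test = setdiff(seq_len(n), tr))
      }
    })
  } else {
    cases <- unique(as.character(data$case_id))
    if (length(cases) < 2) stop("case mode needs at least two cases")
    with_seed(seed, {
      test_cases <- if (repetitions <= length(cases))
        sample(cases, repetitions)
      else c(sample(cases), sample(cases, repetitions - length(cases),
                                   replace = TRUE))
      for (r in seq_len(repetitions)) {
        te <- which(data$case_id == test_cases[r])
        splits[[r]] <- list(train = setdiff(seq_len(nrow(data)), te),
                            test = te, test_case = test_cases[r])
      }
    })
  }
  splits
}
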
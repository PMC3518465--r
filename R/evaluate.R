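#' Repeated split linear-SVM evaluation protocol
#'
#' The classifier bench draws, on each repeat, a random class-balanced
#' training set of `n_train` images and a disjoint balanced test set of
#' `n_test`, picks the SVM cost `C` by line search over `cost_grid` using
#' `folds`-fold cross-validation on the training set, trains a linear SVM at
#' the chosen cost and scores the held-out images; the reported accuracy is
#' the mean over `repeats` such splits.
#'
#' @param n_train,n_test split sizes (each half per class).
#' @param folds cross-validation folds for the cost line search.
#' @param cost_grid candidate costs.
#' @param repeats number of random splits.
#' @param standardize standardize features by training-set mean/sd before
#'   fitting.
#' @param seed integer seed for the split/fold randomness.
#' @return object of class `cv_protocol`.
#' @export
cv_protocol <- function(n_train = 180, n_test = 12, folds = 8,
                        cost_grid = 10^(-3:3), repeats = 100,
                        standardize = TRUE, seed = 1L) {
  stopifnot(n_train %% 2 == 0, n_test %% 2 == 0, folds >= 2,
            length(cost_grid) >= 1, repeats >= 1)
  structure(list(n_train = n_train, n_test = n_test, folds = folds,
                 cost_grid = cost_grid, repeats = repeats,
                 standardize = standardize, seed = as.integer(seed)),
            class = "cv_protocol")
}

line_search_cost <- function(x, y, protocol) {
  n <- nrow(x)
  folds <- sample(rep_len(seq_len(protocol$folds), n))
  acc <- vapply(protocol$cost_grid, function(C) {
    hits <- 0
    for (f in seq_len(protocol$folds)) {
      tr <- folds != f
      if (length(unique(y[tr])) < 2) return(0)
      fit <- e1071::svm(x[tr, , drop = FALSE], y[tr], kernel = "linear",
                        cost = C, scale = FALSE)
      hits <- hits + sum(stats::predict(fit, x[!tr, , drop = FALSE]) == y[!tr])
    }
    hits / n
  }, numeric(1))
  # ties go to the smallest cost (flattest model)
  protocol$cost_grid[which.max(acc)]
}

#' Evaluate one feature model on one task
#'
#' Runs the [cv_protocol()] on a feature matrix with binary labels:
#' repeated balanced 180/12 splits, per-split cost line search by 8-fold CV,
#' linear SVM, held-out accuracy averaged over repeats (defaults).
#'
#' @param features numeric matrix, one row per image (e.g. from
#'   [extract_features()]).
#' @param labels factor (or coercible) with exactly two balanced levels.
#' @param protocol a [cv_protocol()].
#' @param model,task labels stored in the result.
#' @return object of class `model_eval_result`: `mean_accuracy` (percent),
#'   `sd_accuracy`, per-repeat accuracies, chosen costs, protocol.
#' @export
evaluate_model <- function(features, labels, protocol = cv_protocol(),
                           model = attr(features, "model") %||% "model",
                           task = "task") {
  stopifnot(inherits(protocol, "cv_protocol"))
  labels <- factor(labels)
  if (nlevels(labels) != 2)
    stop("need exactly two label levels", call. = FALSE)
  counts <- table(labels)
  if (counts[1] != counts[2])
    stop("unbalanced classes: ", paste(counts, collapse = " vs "),
         call. = FALSE)
  if (any(!is.finite(features)))
    stop("non-finite feature values", call. = FALSE)
  per_class_need <- (protocol$n_train + protocol$n_test) / 2
  if (any(counts < per_class_need))
    stop("need at least ", per_class_need, " images per class for a ",
         protocol$n_train, "/", protocol$n_test, " split", call. = FALSE)
  idx_by_class <- split(seq_along(labels), labels)
  withr::with_seed(protocol$seed, {
    res <- vapply(seq_len(protocol$repeats), function(r) {
      tr_half <- protocol$n_train / 2
      te_half <- protocol$n_test / 2
      picks <- lapply(idx_by_class, function(ix)
        sample(ix, tr_half + te_half))
      tr_idx <- c(picks[[1]][seq_len(tr_half)], picks[[2]][seq_len(tr_half)])
      te_idx <- c(picks[[1]][tr_half + seq_len(te_half)],
                  picks[[2]][tr_half + seq_len(te_half)])
      xtr <- features[tr_idx, , drop = FALSE]
      xte <- features[te_idx, , drop = FALSE]
      if (protocol$standardize) {
        mu <- colMeans(xtr)
        sdv <- apply(xtr, 2, stats::sd)
        sdv[sdv == 0] <- 1
        xtr <- sweep(sweep(xtr, 2, mu), 2, sdv, "/")
        xte <- sweep(sweep(xte, 2, mu), 2, sdv, "/")
      }
      C <- line_search_cost(xtr, labels[tr_idx], protocol)
      fit <- e1071::svm(xtr, labels[tr_idx], kernel = "linear", cost = C,
                        scale = FALSE)
      c(mean(stats::predict(fit, xte) == labels[te_idx]), C)
    }, numeric(2))
  })
  structure(list(model = model, task = task,
                 mean_accuracy = 100 * mean(res[1, ]),
                 sd_accuracy = 100 * stats::sd(res[1, ]),
                 accuracies = 100 * res[1, ], chosen_costs = res[2, ],
                 protocol = protocol),
            class = "model_eval_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.model_eval_result <- function(x, ...) {
  cat(sprintf("<model_eval_result> %s on %s: %.1f%% (sd %.1f) over %d repeats\n",
              x$model, x$task, x$mean_accuracy, x$sd_accuracy,
              x$protocol$repeats))
  invisible(x)
}

#' Rank feature models per task
#'
#' @param results list of [evaluate_model()] results covering every
#'   model/task cell of interest.
#' @param require_complete error unless all four feature models appear on
#'   both tasks.
#' @return tibble ordered by task then descending accuracy, ties broken by
#'   model name.
#' @export
rank_models <- function(results, require_complete = FALSE) {
  tbl <- dplyr::bind_rows(lapply(results, function(r)
    tibble::tibble(model = r$model, task = r$task,
                   mean_accuracy = r$mean_accuracy,
                   sd_accuracy = r$sd_accuracy)))
  if (require_complete) {
    need <- expand.grid(model = c("gist", "weibull", "saliency", "hmax_c1"),
                        task = c("object", "scene"),
                        stringsAsFactors = FALSE)
    have <- paste(tbl$model, tbl$task)
    miss <- setdiff(paste(need$model, need$task), have)
    if (length(miss) > 0)
      stop("missing model/task cell(s): ", paste(miss, collapse = "; "),
           call. = FALSE)
  }
  dplyr::arrange(tbl, task, dplyr::desc(mean_accuracy), model)
}
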
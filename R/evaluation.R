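#' Area under the ROC curve
#'
#' Mann-Whitney formulation: the probability that a randomly chosen positive
#' sample outscores a randomly chosen negative one, counting ties as 1/2.
#'
#' @param scores numeric vector of classifier scores (higher = more
#'   positive).
#' @param labels binary labels: logical, 0/1, or a factor whose second level
#'   is the positive class.
#' @return the AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  y <- as_binary_labels(labels)
  n_pos <- sum(y == 1L); n_neg <- sum(y == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    abort("Both classes must be present to compute an AUC.",
          class = "qdcp_invalid_input")
  }
  r <- rank(scores)  # average ranks handle ties as 1/2
  (sum(r[y == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

as_binary_labels <- function(labels) {
  if (is.logical(labels)) return(as.integer(labels))
  if (is.factor(labels)) {
    if (nlevels(droplevels(labels)) > 2L) {
      abort("Labels must be binary.", class = "qdcp_invalid_input")
    }
    return(as.integer(labels == levels(labels)[nlevels(labels)]))
  }
  u <- sort(unique(labels))
  if (length(u) > 2L) {
    abort("Labels must be binary.", class = "qdcp_invalid_input")
  }
  as.integer(labels == u[length(u)])
}

stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep(seq_len(k), length.out = length(idx))
  }
  fold
}

# --- classifiers -----------------------------------------------------------
# Each fit_* returns a model; predict_scores_* returns a list(score, pred)
# with score oriented so larger = more likely positive.

fit_fld <- function(x, y) {
  x0 <- x[y == 0L, , drop = FALSE]
  x1 <- x[y == 1L, , drop = FALSE]
  m0 <- colMeans(x0); m1 <- colMeans(x1)
  c0 <- crossprod(sweep(x0, 2, m0))
  c1 <- crossprod(sweep(x1, 2, m1))
  sw <- (c0 + c1) / max(1, nrow(x) - 2)
  w <- MASS::ginv(sw) %*% (m1 - m0)
  list(w = w, cutoff = sum(((m0 + m1) / 2) * w))
}

predict_fld <- function(model, x) {
  s <- as.vector(x %*% model$w)
  list(score = s, pred = as.integer(s > model$cutoff))
}

fit_svm_rbf <- function(x, y, gamma, cost) {
  fit <- e1071::svm(x = x, y = factor(y, levels = c(0, 1)), kernel = "radial",
                    gamma = gamma, cost = cost, scale = FALSE)
  dv <- attr(stats::predict(fit, x, decision.values = TRUE),
             "decision.values")[, 1]
  flip <- mean(dv[y == 1L]) < mean(dv[y == 0L])
  list(fit = fit, flip = flip)
}

predict_svm_rbf <- function(model, x) {
  pr <- stats::predict(model$fit, x, decision.values = TRUE)
  s <- attr(pr, "decision.values")[, 1]
  if (model$flip) s <- -s
  list(score = s, pred = as.integer(as.character(pr)))
}

knn_scores <- function(x_train, y_train, x_test, k, metric) {
  if (metric == "euclidean") {
    d2 <- outer(rowSums(x_test^2), rowSums(x_train^2), "+") -
      2 * x_test %*% t(x_train)
    d <- sqrt(pmax(d2, 0))
  } else {
    d <- t(apply(x_test, 1, function(r) colSums(abs(t(x_train) - r))))
    if (nrow(x_test) == 1L) d <- matrix(d, nrow = 1)
  }
  k <- min(k, length(y_train))
  score <- apply(d, 1, function(row) mean(y_train[order(row)[seq_len(k)]]))
  list(score = score, pred = as.integer(score > 0.5))
}

#' Default classifier hyper-parameter grids
#'
#' RBF-SVM: kernel width as multiples `{0.1, 1, 10}` of the median pairwise
#' training distance (so `gamma = 1 / (2 sigma^2)`) crossed with box
#' constraints `{0.1, 1, 10, 100}`. KNN: `k in {1, 3, 5, 7, 9}` crossed with
#' Euclidean and city-block metrics. FLD has no hyper-parameters.
#'
#' @param classifier one of `"fld"`, `"svm_rbf"`, `"knn"`.
#' @return a data frame of hyper-parameter combinations.
#' @export
default_grid <- function(classifier = c("fld", "svm_rbf", "knn")) {
  classifier <- match.arg(classifier)
  switch(classifier,
    fld = data.frame(dummy = 1),
    svm_rbf = expand.grid(sigma_mult = c(0.1, 1, 10),
                          cost = c(0.1, 1, 10, 100)),
    knn = expand.grid(k = c(1L, 3L, 5L, 7L, 9L),
                      metric = c("euclidean", "manhattan"),
                      stringsAsFactors = FALSE)
  )
}

#' Default similarity-threshold search grid
#'
#' `{0.55, 0.60, ..., 1.00}`, covering the coarse-to-fine sweep range over
#' which the descriptor is typically examined.
#' @return numeric vector of thresholds.
#' @export
default_t_o_grid <- function() seq(0.55, 1.00, by = 0.05)

# fit + score one configuration on one split
eval_config <- function(classifier, x_train, y_train, x_test, grid_row,
                        sigma0 = NULL) {
  if (classifier == "fld") {
    model <- fit_fld(x_train, y_train)
    return(predict_fld(model, x_test))
  }
  if (classifier == "svm_rbf") {
    sigma <- grid_row$sigma_mult * sigma0
    gamma <- 1 / (2 * max(sigma, 1e-12)^2)
    model <- fit_svm_rbf(x_train, y_train, gamma = gamma, cost = grid_row$cost)
    return(predict_svm_rbf(model, x_test))
  }
  knn_scores(x_train, y_train, x_test, k = grid_row$k,
             metric = grid_row$metric)
}

median_pairwise_dist <- function(x) {
  m <- stats::median(stats::dist(x))
  if (!is.finite(m) || m <= 0) 1 else m
}

#' Repeated nested cross-validation of a descriptor/classifier pair
#'
#' The evaluation protocol: stratified outer k-fold cross-validation
#' estimates generalization; within each outer training split an inner
#' stratified cross-validation jointly selects the descriptor threshold (one
#' feature set per candidate threshold) and the classifier hyper-parameters
#' by inner accuracy; the winning configuration is refit on the full outer
#' training split and scored on the held-out fold (accuracy and ROC-AUC).
#' The whole procedure is repeated with fresh fold assignments, and
#' statistics aggregate all `n_repeats * outer_k` fold scores.
#'
#' @param feature_sets a single feature matrix / feature tibble (from
#'   [extract_features()]), or a named list of feature matrices, one per
#'   candidate descriptor configuration (e.g. per threshold, from
#'   [feature_set_grid()]). All matrices share rows (samples).
#' @param labels binary class labels (factor second level = positive).
#' @param classifier `"fld"`, `"svm_rbf"`, or `"knn"`.
#' @param outer_k,inner_k outer and inner fold counts.
#' @param n_repeats repetitions of the outer cross-validation.
#' @param seed master seed; all fold assignments derive from it.
#' @param grid hyper-parameter data frame (default [default_grid()]).
#' @return a `qdcp_eval` object; see [tidy()] for per-fold results and
#'   [glance()] for the mean/sd summary.
#' @export
nested_cv <- function(feature_sets, labels,
                      classifier = c("fld", "svm_rbf", "knn"),
                      outer_k = 10, inner_k = 5, n_repeats = 10, seed = 1L,
                      grid = NULL) {
  classifier <- match.arg(classifier)
  if (is.data.frame(feature_sets)) feature_sets <- feature_matrix(feature_sets)
  if (is.matrix(feature_sets)) feature_sets <- list(default = feature_sets)
  if (is.null(names(feature_sets))) {
    names(feature_sets) <- sprintf("set_%02d", seq_along(feature_sets))
  }
  y <- as_binary_labels(labels)
  n <- length(y)
  if (any(vapply(feature_sets, nrow, 1L) != n)) {
    abort("Feature sets and labels disagree on the number of samples.",
          class = "qdcp_invalid_input")
  }
  if (length(unique(y)) < 2L) {
    abort("Both classes must be present.", class = "qdcp_invalid_input")
  }
  if (min(table(y)) < outer_k) {
    abort("Need at least `outer_k` samples per class.",
          class = "qdcp_invalid_input")
  }
  grid <- grid %||% default_grid(classifier)

  repeat_seeds <- with_local_seed(seed,
                                  sample.int(.Machine$integer.max - 1L,
                                             n_repeats))
  results <- vector("list", n_repeats)
  for (r in seq_len(n_repeats)) {
    results[[r]] <- with_local_seed(repeat_seeds[r], {
      outer_fold <- stratified_folds(y, outer_k)
      fold_rows <- vector("list", outer_k)
      for (o in seq_len(outer_k)) {
        test_idx <- which(outer_fold == o)
        train_idx <- which(outer_fold != o)
        y_tr <- y[train_idx]
        inner_fold <- stratified_folds(y_tr, inner_k)

        sigma0 <- NULL
        best <- list(acc = -Inf, set = NULL, row = NULL)
        for (s in names(feature_sets)) {
          x_all <- feature_sets[[s]]
          x_tr <- x_all[train_idx, , drop = FALSE]
          if (classifier == "svm_rbf") sigma0 <- median_pairwise_dist(x_tr)
          for (g in seq_len(nrow(grid))) {
            correct <- 0L
            for (f in seq_len(inner_k)) {
              vi <- which(inner_fold == f)
              ti <- which(inner_fold != f)
              res <- eval_config(classifier,
                                 x_tr[ti, , drop = FALSE], y_tr[ti],
                                 x_tr[vi, , drop = FALSE],
                                 grid[g, , drop = FALSE], sigma0)
              correct <- correct + sum(res$pred == y_tr[vi])
            }
            acc <- correct / length(y_tr)
            if (acc > best$acc) {
              best <- list(acc = acc, set = s, row = grid[g, , drop = FALSE],
                           sigma0 = sigma0)
            }
          }
        }

        x_best <- feature_sets[[best$set]]
        res <- eval_config(classifier,
                           x_best[train_idx, , drop = FALSE], y_tr,
                           x_best[test_idx, , drop = FALSE],
                           best$row, best$sigma0)
        fold_rows[[o]] <- tibble(
          repeat_id = r, fold = o,
          acc = mean(res$pred == y[test_idx]),
          auc = roc_auc(res$score, y[test_idx]),
          feature_set = best$set,
          hyper = paste(names(best$row), unlist(lapply(best$row, format)),
                        sep = "=", collapse = ", "),
          inner_acc = best$acc
        )
      }
      dplyr::bind_rows(fold_rows)
    })
  }
  structure(
    list(results = dplyr::bind_rows(results), classifier = classifier,
         outer_k = outer_k, inner_k = inner_k, n_repeats = n_repeats,
         seed = seed),
    class = "qdcp_eval"
  )
}

#' @export
print.qdcp_eval <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<qdcp_eval: %s, %d x %d-fold nested CV>\n  ACC %.3f +/- %.3f   AUC %.3f +/- %.3f\n",
    x$classifier, x$n_repeats, x$outer_k,
    g$acc_mean, g$acc_sd, g$auc_mean, g$auc_sd))
  invisible(x)
}
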
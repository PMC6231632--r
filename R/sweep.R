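#' Sensitivity sweep of the similarity threshold
#'
#' Evaluates the counter-color descriptor at each threshold of a grid with a
#' plain (non-nested) stratified k-fold cross-validation and a fixed
#' classifier configuration, producing the accuracy-versus-threshold curve
#' used to examine the coarse-to-fine behaviour of the code.
#'
#' @param images list of RGB images.
#' @param labels binary class labels.
#' @param t_o_grid thresholds to sweep (default [default_t_o_grid()]).
#' @param classifier `"fld"` (default; no hyper-parameters), `"svm_rbf"`
#'   (median-heuristic width, cost 1), or `"knn"` (k = 5, Euclidean).
#' @param folds number of CV folds.
#' @param n_repeats CV repetitions.
#' @param seed RNG seed.
#' @param spec,color_space,normalize descriptor settings, see
#'   [qdcp_feature()].
#' @return a `qdcp_sweep` tibble: `t_o`, `angle_deg`, `acc_mean`, `acc_sd`,
#'   `auc_mean`, `auc_sd`.
#' @export
threshold_sweep <- function(images, labels, t_o_grid = default_t_o_grid(),
                            classifier = c("fld", "svm_rbf", "knn"),
                            folds = 10, n_repeats = 1, seed = 1L,
                            spec = neighborhood_spec(),
                            color_space = "ycbcr", normalize = TRUE) {
  classifier <- match.arg(classifier)
  y <- as_binary_labels(labels)
  sets <- feature_set_grid(images, "qdcp", t_o_grid = t_o_grid, spec = spec,
                           color_space = color_space, normalize = normalize)
  fixed_row <- switch(classifier,
    fld = data.frame(dummy = 1),
    svm_rbf = data.frame(sigma_mult = 1, cost = 1),
    knn = data.frame(k = 5L, metric = "euclidean",
                     stringsAsFactors = FALSE)
  )
  repeat_seeds <- with_local_seed(seed,
                                  sample.int(.Machine$integer.max - 1L,
                                             n_repeats))
  rows <- vector("list", length(t_o_grid))
  for (i in seq_along(t_o_grid)) {
    x <- sets[[i]]
    accs <- c(); aucs <- c()
    for (r in seq_len(n_repeats)) {
      fold <- with_local_seed(repeat_seeds[r], stratified_folds(y, folds))
      for (f in seq_len(folds)) {
        te <- which(fold == f); tr <- which(fold != f)
        sigma0 <- if (classifier == "svm_rbf") {
          median_pairwise_dist(x[tr, , drop = FALSE])
        } else NULL
        res <- eval_config(classifier, x[tr, , drop = FALSE], y[tr],
                           x[te, , drop = FALSE], fixed_row, sigma0)
        accs <- c(accs, mean(res$pred == y[te]))
        aucs <- c(aucs, roc_auc(res$score, y[te]))
      }
    }
    rows[[i]] <- tibble(
      t_o = t_o_grid[i], angle_deg = threshold_to_angle(t_o_grid[i]),
      acc_mean = mean(accs), acc_sd = sd(accs),
      auc_mean = mean(aucs), auc_sd = sd(aucs)
    )
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("qdcp_sweep", class(out))
  attr(out, "classifier") <- classifier
  out
}
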
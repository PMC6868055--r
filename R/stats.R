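#' Column-wise z-scoring
#'
#' Centres each column to mean 0 and scales to sample standard deviation 1.
#'
#' @param x numeric matrix or data frame of features.
#' @return numeric matrix of the same shape.
#' @export
zscore <- function(x) {
  x <- as.matrix(x)
  s <- apply(x, 2L, sd)
  if (any(s == 0))
    stop("constant feature column(s): ",
         paste(colnames(x)[s == 0], collapse = ", "))
  scale(x, center = TRUE, scale = s)[, , drop = FALSE]
}

#' PCA-loading-based feature importance
#'
#' Performs PCA on the (z-scored) feature matrix and scores each feature as
#' the sum over retained components of its squared loading times the
#' percentage of variance that component explains:
#' `importance_i = sum_j coeff[i, j]^2 * explained[j]`.
#' With all components retained the scores sum to the total explained
#' variance (100%), since the loadings matrix is orthonormal. Scores are
#' invariant to loading sign flips and to row permutations.
#'
#' Component retention matters: summed over *all* components the score
#' reduces algebraically to each feature's share of total variance, which
#' is identical for every column of a z-scored matrix — the ranking is
#' only informative when the high-variance components are retained and the
#' noise floor is not. `retain = "kaiser"` keeps components with
#' above-average variance and is what the feature-evaluation protocol
#' uses; `retain = "all"` keeps everything (and then the scores sum to
#' 100).
#'
#' @param x numeric matrix, observations x features (typically z-scored;
#'   `scale.` is not applied here).
#' @param retain `"all"`, `"kaiser"` (components with above-average
#'   variance), or an integer number of leading components.
#' @param tol relative variance below which trailing components are dropped
#'   (with a warning) as numerically rank deficient.
#' @return an object of class `pca_importance`: a ranking data frame
#'   (`feature`, `score`, `rank`), plus `loadings` and `explained`
#'   (percent) used.
#' @export
pca_importance <- function(x, retain = "all", tol = 1e-12) {
  x <- as.matrix(x)
  if (nrow(x) <= ncol(x))
    stop("need more observations than features for PCA importance")
  p <- prcomp(x, center = TRUE, scale. = FALSE)
  v <- p$sdev^2
  keep <- v > tol * v[1L]
  if (!all(keep))
    warning(sprintf("dropped %d near-zero-variance component(s)",
                    sum(!keep)))
  if (is.numeric(retain)) {
    keep <- keep & seq_along(v) <= retain
  } else if (identical(retain, "kaiser")) {
    keep <- keep & v > mean(v)
  } else if (!identical(retain, "all")) {
    stop("retain must be \"all\", \"kaiser\" or an integer")
  }
  expl <- 100 * v / sum(v)
  coeff <- p$rotation[, keep, drop = FALSE]
  score <- as.vector(coeff^2 %*% expl[keep])
  nm <- colnames(x)
  if (is.null(nm)) nm <- paste0("feature_", seq_along(score))
  ranking <- data.frame(feature = nm, score = score,
                        rank = rank(-score, ties.method = "first"))
  ranking <- ranking[order(ranking$rank), , drop = FALSE]
  rownames(ranking) <- NULL
  structure(list(ranking = ranking, loadings = coeff,
                 explained = expl[keep]),
            class = "pca_importance")
}

#' @export
print.pca_importance <- function(x, ...) {
  cat("PCA-based feature importance (squared loadings x explained %):\n")
  print(x$ranking, row.names = FALSE)
  invisible(x)
}

# Stratified index split: fraction `frac` of each class into the first set.
stratified_split <- function(labels, frac, seed) {
  withr::with_seed(as.integer(seed), {
    train <- unlist(lapply(split(seq_along(labels), labels), function(ix) {
      n_tr <- round(length(ix) * frac)
      sample(ix, n_tr)
    }), use.names = FALSE)
    list(train = sort(train),
         test = setdiff(seq_along(labels), train))
  })
}

#' Train and test a Gaussian-kernel SVM once
#'
#' Stratified random 70/30 split, radial-basis (Gaussian) kernel SVM
#' trained on the selected feature columns, held-out accuracy returned.
#' If a training fold degenerates to one class the split is retried with
#' the next seed.
#'
#' @param x numeric feature matrix.
#' @param labels binary class labels.
#' @param feature_subset column names or indices to use (default: all).
#' @param split training fraction (default 0.7).
#' @param seed integer seed for the split.
#' @param cost,gamma SVM hyper-parameters (defaults: cost 1,
#'   gamma 1/n_features as in libsvm).
#' @return held-out accuracy in `[0, 1]`.
#' @export
train_gaussian_svm <- function(x, labels, feature_subset = NULL,
                               split = 0.7, seed = 1L, cost = 1,
                               gamma = NULL) {
  x <- as.matrix(x)
  labels <- factor(labels)
  if (nlevels(labels) != 2L) stop("binary labels required")
  if (is.null(feature_subset)) feature_subset <- seq_len(ncol(x))
  xs <- x[, feature_subset, drop = FALSE]
  if (ncol(xs) == 0L) stop("feature subset is empty")
  if (is.null(gamma)) gamma <- 1 / ncol(xs)
  for (try in 0:9) {
    sp <- stratified_split(labels, split, seed + try)
    if (length(unique(labels[sp$train])) == 2L) break
  }
  fit <- e1071::svm(xs[sp$train, , drop = FALSE], labels[sp$train],
                    kernel = "radial", cost = cost, gamma = gamma,
                    scale = FALSE)
  pred <- stats::predict(fit, xs[sp$test, , drop = FALSE])
  mean(pred == labels[sp$test])
}

#' Repeated SVM accuracy distribution
#'
#' Repeats [train_gaussian_svm()] over `n_reps` independent stratified
#' splits (per-repetition seeds derived from the master seed), yielding
#' the accuracy distribution used to compare feature subsets.
#'
#' @inheritParams train_gaussian_svm
#' @param n_reps repetitions (default 30).
#' @param subset_label label stored with the distribution.
#' @return an object of class `accuracy_distribution`: numeric accuracies
#'   with `seeds` and `subset` attributes.
#' @export
repeated_accuracy <- function(x, labels, feature_subset = NULL,
                              n_reps = 30L, seed = 1L, split = 0.7,
                              cost = 1, gamma = NULL,
                              subset_label = "features") {
  seeds <- derive_seeds(seed, n_reps)
  acc <- vapply(seeds, function(s)
    train_gaussian_svm(x, labels, feature_subset, split, s, cost, gamma),
    numeric(1L))
  structure(acc, class = "accuracy_distribution",
            seeds = seeds, subset = subset_label)
}

#' @export
print.accuracy_distribution <- function(x, ...) {
  cat(sprintf("accuracy over %d SVM repetitions [%s]: median %.3f (IQR %.3f-%.3f)\n",
              length(x), attr(x, "subset"), median(unclass(x)),
              quantile(unclass(x), 0.25), quantile(unclass(x), 0.75)))
  invisible(x)
}

#' Compare two accuracy distributions
#'
#' Two-sided Wilcoxon rank-sum test on two accuracy distributions.
#'
#' @param a,b numeric accuracy vectors.
#' @return the p-value.
#' @export
compare_distributions <- function(a, b) {
  p <- suppressWarnings(wilcox.test(as.numeric(a), as.numeric(b),
                                    exact = FALSE)$p.value)
  # fully tied samples degenerate to a zero-variance statistic
  if (is.nan(p)) 1 else p
}
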
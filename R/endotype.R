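# Endotype discovery: k-means with restarts, cluster-number diagnostics
# (within-cluster sum of squares, mean silhouette, gap statistic with the
# one-standard-error rule), the label-1-is-smaller-cluster convention, and
# internal validation by split and nested cross-validation.

#' Best-of-restarts k-means clustering
#'
#' Hartigan-Wong k-means (as in [stats::kmeans()]) with `n_restarts` random
#' starts; the solution with minimal total within-cluster sum of squares is
#' returned.
#'
#' @param x Samples x features numeric matrix (row names = sample ids).
#' @param k Number of clusters.
#' @param seed Integer seed.
#' @param n_restarts Number of random restarts (default 25).
#' @return List with `labels` (integer cluster per sample, named), `centers`,
#'   `wss` (total within-cluster SS), `sizes`, `seed`, `n_restarts`.
#' @export
kmeans_endotypes <- function(x, k, seed = 1L, n_restarts = 25L) {
  x <- as.matrix(x)
  if (k < 1) stop("k must be >= 1")
  if (k > nrow(x)) stop("k exceeds the number of samples")
  set.seed(seed)
  fit <- stats::kmeans(x, centers = k, nstart = n_restarts, iter.max = 300,
                       algorithm = "Hartigan-Wong")
  labels <- fit$cluster
  if (!is.null(rownames(x))) names(labels) <- rownames(x)
  list(labels = labels, centers = fit$centers, wss = fit$tot.withinss,
       sizes = as.integer(fit$size), seed = as.integer(seed),
       n_restarts = as.integer(n_restarts))
}

#' Gap statistic over a grid of cluster numbers
#'
#' Gap(k) = mean_b log W*_kb - log W_k, with B reference data sets drawn
#' uniformly on the principal-axes-aligned bounding box of the data
#' (via [cluster::clusGap()] with `spaceH0 = "scaledPCA"`), and
#' s_k = sd_b(log W*_kb) * sqrt(1 + 1/B). The selected k is the smallest k
#' with Gap(k) >= Gap(k+1) - s_{k+1} (the one-standard-error rule).
#'
#' @param x Samples x features matrix.
#' @param k_max Largest cluster number evaluated (grid is 1..k_max).
#' @param B Number of reference data sets (default 50).
#' @param seed Integer seed.
#' @param n_restarts Restarts for each internal k-means fit.
#' @return A `cluster_diagnostics` list: `k_grid`, `wss`, `log_wss`, `gap`,
#'   `gap_se`, `mean_silhouette`, `k_selected`.
#' @export
gap_statistic <- function(x, k_max = 6L, B = 50L, seed = 1L, n_restarts = 10L) {
  x <- as.matrix(x)
  if (B < 2) stop("B must be >= 2")
  if (k_max >= nrow(x)) stop("k_max must be < number of samples")
  set.seed(seed)
  km_fun <- function(x, k) stats::kmeans(x, k, nstart = n_restarts,
                                         iter.max = 300)
  cg <- cluster::clusGap(x, FUNcluster = km_fun, K.max = k_max, B = B,
                         spaceH0 = "scaledPCA", verbose = FALSE)
  tab <- cg$Tab
  k_grid <- seq_len(k_max)
  k_sel <- cluster::maxSE(tab[, "gap"], tab[, "SE.sim"],
                          method = "Tibs2001SEmax")
  d <- stats::dist(x)
  sil <- vapply(k_grid, function(k) {
    if (k == 1) return(NA_real_)
    set.seed(seed + k)
    labs <- km_fun(x, k)$cluster
    if (length(unique(labs)) < 2) return(NA_real_)
    mean(cluster::silhouette(labs, d)[, "sil_width"])
  }, numeric(1))
  structure(list(k_grid = k_grid, wss = exp(tab[, "logW"]),
                 log_wss = tab[, "logW"], gap = tab[, "gap"],
                 gap_se = tab[, "SE.sim"], mean_silhouette = sil,
                 k_selected = as.integer(k_sel)),
            class = "cluster_diagnostics")
}

#' Mean silhouette width of a clustering
#'
#' Euclidean silhouette: per sample (b - a) / max(a, b) with a the mean
#' intra-cluster distance and b the smallest mean distance to another
#' cluster; samples in singleton clusters contribute 0
#' (via [cluster::silhouette()]).
#'
#' @param x Samples x features matrix.
#' @param labels Integer cluster labels.
#' @return Mean silhouette width.
#' @export
silhouette_mean <- function(x, labels) {
  if (length(unique(labels)) < 2)
    stop("silhouette requires at least two clusters")
  mean(cluster::silhouette(as.integer(labels), stats::dist(as.matrix(x)))[, "sil_width"])
}

#' Assign endotype labels with the label-1-is-smaller convention
#'
#' Runs [kmeans_endotypes()] with k = 2 (optionally after standardizing
#' features to unit variance) and relabels clusters so endotype 1 is the
#' smaller cluster, matching the direction of the published 122/260 split.
#' Ties go to the cluster containing the lexicographically smallest sample
#' id.
#'
#' @param x Samples x features matrix (rows named by sample id).
#' @param k Number of clusters (the downstream pipeline assumes 2).
#' @param seed Integer seed.
#' @param n_restarts Restarts passed to [kmeans_endotypes()].
#' @param standardize Scale features to unit variance first (default TRUE).
#' @return An `endotype_result`: `labels` (1/2 per sample, named), `centers`,
#'   `sizes` (per final label), `wss`, `seed`, `n_restarts`.
#' @export
assign_endotypes <- function(x, k = 2L, seed = 1L, n_restarts = 25L,
                             standardize = TRUE) {
  x <- as.matrix(x)
  if (standardize) {
    sds <- apply(x, 2, stats::sd)
    sds[sds == 0] <- 1
    x <- sweep(x, 2, sds, "/")
  }
  fit <- kmeans_endotypes(x, k = k, seed = seed, n_restarts = n_restarts)
  sizes <- tabulate(fit$labels, nbins = k)
  ord <- order(sizes)
  if (k == 2 && sizes[1] == sizes[2]) {
    # tie: endotype 1 is the cluster holding the lexicographically smallest id
    first <- fit$labels[order(names(fit$labels))[1]]
    ord <- c(first, setdiff(1:2, first))
  }
  relabel <- integer(k)
  relabel[ord] <- seq_len(k)
  labels <- relabel[fit$labels]
  names(labels) <- names(fit$labels)
  structure(list(labels = labels, centers = fit$centers[ord, , drop = FALSE],
                 sizes = tabulate(labels, nbins = k), wss = fit$wss,
                 seed = fit$seed, n_restarts = fit$n_restarts),
            class = "endotype_result")
}

#' @export
print.endotype_result <- function(x, ...) {
  cat(sprintf("endotype_result: %d samples, sizes %s (endotype 1 = smaller)\n",
              length(x$labels), paste(x$sizes, collapse = "/")))
  invisible(x)
}

stratified_folds <- function(y, k, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep(seq_len(k), length.out = length(idx))
  }
  fold
}

#' Validate endotype labels by split and nested cross-validation
#'
#' (a) A stratified 2/3 training - 1/3 validation split; an elastic-net
#' logistic classifier (glmnet, alpha = 0.5, penalty chosen by internal CV)
#' is fit on the training portion and `split_accuracy` is its held-out
#' accuracy. (b) Nested cross-validation: stratified outer 5-fold, inner CV
#' tunes the penalty path; `cv_accuracy` pools outer-fold predictions.
#'
#' @param x Samples x features matrix.
#' @param labels Endotype labels (two classes).
#' @param seed Integer seed.
#' @param n_outer_folds Outer folds for the nested CV (default 5).
#' @return A `validation_report`: `split_accuracy`, `cv_accuracy`,
#'   `split_fractions`, `n_outer_folds`.
#' @export
validate_endotypes <- function(x, labels, seed = 1L, n_outer_folds = 5L) {
  x <- as.matrix(x)
  y <- as.integer(factor(labels))
  if (length(unique(y)) != 2) stop("validation requires exactly two classes")
  if (min(table(y)) < n_outer_folds)
    stop("stratification error: a class has fewer samples than folds")

  # train/validation split
  fold3 <- stratified_folds(y, 3L, seed)
  train <- fold3 != 1L
  if (length(unique(y[train])) < 2 || length(unique(y[!train])) < 2)
    stop("stratification error: a class is absent from a split")
  set.seed(seed)
  cv <- glmnet::cv.glmnet(x[train, ], y[train], family = "binomial",
                          alpha = 0.5, nfolds = 5)
  pred <- as.integer(stats::predict(cv, x[!train, ], s = "lambda.min",
                                    type = "class"))
  split_accuracy <- mean(pred == y[!train])

  # nested CV
  fold <- stratified_folds(y, n_outer_folds, seed + 1L)
  correct <- logical(length(y))
  for (f in seq_len(n_outer_folds)) {
    tr <- fold != f
    set.seed(seed + 10L + f)
    cvf <- glmnet::cv.glmnet(x[tr, ], y[tr], family = "binomial",
                             alpha = 0.5, nfolds = 5)
    p <- as.integer(stats::predict(cvf, x[!tr, , drop = FALSE],
                                   s = "lambda.min", type = "class"))
    correct[!tr] <- p == y[!tr]
  }
  structure(list(split_accuracy = split_accuracy,
                 cv_accuracy = mean(correct),
                 split_fractions = c(train = 2 / 3, validation = 1 / 3),
                 n_outer_folds = as.integer(n_outer_folds)),
            class = "validation_report")
}
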
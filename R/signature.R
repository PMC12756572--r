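# Minimal gene-signature selection: forward-selection partial least squares
# (greedy univariate selection with rank-one deflation and a Bonferroni
# stopping rule), exhaustive search for the best 1/2/3-gene combination
# under a logistic combination score, and ROC/Youden threshold optimization.

#' Forward-selection PLS variable selection
#'
#' Iteratively regresses the current response residual on each remaining
#' (deflated) gene, selects the gene with the smallest coefficient p-value,
#' and stops when that p-value exceeds `alpha / (number of remaining genes)`
#' (Bonferroni) or `max_k` genes are selected. After each selection the gene
#' matrix is deflated by projecting out the selected gene's component
#' (rank-one deflation x <- x - t t'x / ||t||^2 with t the selected column)
#' and the response residual is updated, so collinear copies of a selected
#' gene carry no remaining signal.
#'
#' @param x Samples x genes matrix (column names = gene ids).
#' @param y Binary response (endotype indicator).
#' @param max_k Maximum number of genes to select (default 10).
#' @param alpha Significance level before the Bonferroni correction
#'   (default 0.05).
#' @return An `fspls_trace`: `selected_genes` (ordered), `step_p`,
#'   `step_coefficient`, `stop_reason` ("max_reached" or "no_significant").
#' @export
fspls_select <- function(x, y, max_k = 10L, alpha = 0.05) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  if (stats::var(y) == 0) stop("constant response")
  if (is.null(colnames(x))) colnames(x) <- paste0("g", seq_len(ncol(x)))
  n <- nrow(x)
  r <- y - mean(y)
  X <- scale(x, center = TRUE, scale = FALSE)
  remaining <- colnames(x)
  selected <- character(0); step_p <- numeric(0); step_b <- numeric(0)
  stop_reason <- "max_reached"
  while (length(selected) < max_k) {
    ssx <- colSums(X[, remaining, drop = FALSE]^2)
    live <- remaining[ssx > 1e-12 * n]
    if (length(live) == 0) { stop_reason <- "no_significant"; break }
    ssx <- ssx[live]
    xr <- as.numeric(crossprod(X[, live, drop = FALSE], r))
    b <- xr / ssx
    rss <- sum(r^2) - b^2 * ssx
    rss[rss < 0] <- 0
    df <- n - 2
    se <- sqrt(rss / df / ssx)
    tstat <- ifelse(se > 0, b / se, Inf)
    pvals <- 2 * stats::pt(-abs(tstat), df = df)
    j <- which.min(pvals)
    if (pvals[j] > alpha / length(live)) { stop_reason <- "no_significant"; break }
    g <- live[j]
    selected <- c(selected, g)
    step_p <- c(step_p, pvals[j])
    step_b <- c(step_b, b[j])
    tvec <- X[, g]
    nt <- sum(tvec^2)
    # deflate gene matrix and response residual on the selected component
    proj <- crossprod(X, tvec) / nt
    X <- X - tcrossprod(tvec, as.numeric(proj))
    r <- r - tvec * sum(tvec * r) / nt
    remaining <- setdiff(remaining, g)
    if (length(remaining) == 0) break
  }
  structure(list(selected_genes = selected, step_p = step_p,
                 step_coefficient = step_b, stop_reason = stop_reason),
            class = "fspls_trace")
}

#' ROC curve by threshold sweep
#'
#' Thresholds are the midpoints between consecutive distinct scores plus
#' -Inf and +Inf; a sample is called positive when its score is at or above
#' the threshold. AUROC is computed by the trapezoid rule and equals the
#' normalized Mann-Whitney U statistic.
#'
#' @param scores Numeric scores (higher = more class-1-like).
#' @param labels Binary labels (1 = positive class).
#' @return List: `thresholds`, `fpr`, `tpr`, `auroc`.
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.integer(labels == max(labels))
  if (length(unique(labels)) < 2) stop("both classes required")
  s <- sort(unique(scores))
  thresholds <- c(-Inf, if (length(s) > 1) (s[-1] + s[-length(s)]) / 2, Inf)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  tpr <- vapply(thresholds, function(t) sum(scores >= t & labels == 1) / n1,
                numeric(1))
  fpr <- vapply(thresholds, function(t) sum(scores >= t & labels == 0) / n0,
                numeric(1))
  ord <- order(fpr, tpr)
  auroc <- sum(diff(fpr[ord]) * (tpr[ord][-1] + tpr[ord][-length(ord)]) / 2)
  list(thresholds = thresholds, fpr = fpr, tpr = tpr, auroc = auroc)
}

youden_threshold <- function(scores, labels) {
  roc <- roc_curve(scores, labels)
  sens <- roc$tpr
  spec <- 1 - roc$fpr
  j <- sens + spec - 1
  best <- which(j == max(j))
  # ties resolved toward the higher threshold
  pick <- best[which.max(roc$thresholds[best])]
  list(threshold = roc$thresholds[pick], sensitivity = sens[pick],
       specificity = spec[pick], youden_j = j[pick], auroc = roc$auroc)
}

#' Best 1/2/3-gene combination panels
#'
#' Exhaustively enumerates every subset of each requested size among the
#' candidate genes, fits a logistic combination score, computes the ROC by
#' threshold sweep, and keeps the subset maximizing AUROC (ties broken by
#' lexicographic subset order). Within the winning subset the reporting
#' threshold maximizes the Youden index J = sensitivity + specificity - 1
#' (ties toward the higher threshold). Perfectly separated logistic fits
#' fall back to the linear-regression score, flagged in the result.
#'
#' @param x Samples x genes matrix.
#' @param y Binary endotype labels (1 = endotype 1 / positive class).
#' @param candidate_genes Candidate gene ids (at most 15).
#' @param sizes Panel sizes to search (default 1:3).
#' @return Named list (by size) of `signature_panel` objects: `genes`,
#'   `coefficients`, `threshold`, `sensitivity`, `specificity`, `auroc`,
#'   `youden_j`, `separation_fallback`.
#' @export
best_combination <- function(x, y, candidate_genes, sizes = 1:3) {
  x <- as.matrix(x)
  if (length(candidate_genes) > 15)
    stop("at most 15 candidate genes (exhaustive enumeration bound)")
  missing <- setdiff(candidate_genes, colnames(x))
  if (length(missing)) stop("candidate genes absent from x: ",
                            paste(missing, collapse = ", "))
  y <- as.integer(y == max(y))
  score_subset <- function(genes) {
    dat <- data.frame(y = y, x[, genes, drop = FALSE], check.names = FALSE)
    fit <- suppressWarnings(stats::glm(y ~ ., data = dat, family = stats::binomial()))
    sep <- suppressWarnings(max(abs(stats::coef(fit)[-1]), na.rm = TRUE)) > 1e3
    if (sep || !fit$converged) {
      lf <- stats::lm(y ~ ., data = dat)
      list(score = as.numeric(stats::fitted(lf)), coef = stats::coef(lf),
           fallback = TRUE)
    } else {
      eta <- as.numeric(stats::predict(fit, type = "link"))
      list(score = eta, coef = stats::coef(fit), fallback = FALSE)
    }
  }
  out <- list()
  for (sz in sizes) {
    combos <- utils::combn(sort(candidate_genes), sz, simplify = FALSE)
    best <- NULL
    for (genes in combos) {
      sc <- score_subset(genes)
      auc <- roc_curve(sc$score, y)$auroc
      if (is.null(best) || auc > best$auc + 1e-12) {
        best <- list(genes = genes, auc = auc, sc = sc)
      }
    }
    yt <- youden_threshold(best$sc$score, y)
    out[[as.character(sz)]] <- structure(list(
      genes = best$genes, coefficients = best$sc$coef,
      threshold = yt$threshold, sensitivity = yt$sensitivity,
      specificity = yt$specificity, auroc = yt$auroc,
      youden_j = yt$youden_j, separation_fallback = best$sc$fallback),
      class = "signature_panel")
  }
  out
}

#' @export
print.signature_panel <- function(x, ...) {
  cat(sprintf("signature_panel: %s | AUROC %.3f | sens %.3f spec %.3f (Youden J %.3f)\n",
              paste(x$genes, collapse = "+"), x$auroc, x$sensitivity,
              x$specificity, x$youden_j))
  invisible(x)
}
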
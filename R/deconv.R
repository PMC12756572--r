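# Bulk immune-cell deconvolution: linear-kernel nu-support-vector regression
# of the standardized mixture on a cell-type signature matrix, with the
# non-negative-least-squares solver as a deterministic alternative engine,
# and per-cell-type association of estimated fractions with BASICq.

#' Deconvolve one bulk sample against a signature matrix
#'
#' Restricts to genes shared between the sample and the signature, z-scores
#' the mixture and each signature column over those genes, and fits a
#' linear-kernel nu-SVR of the mixture on the signature columns for each
#' candidate nu. Negative coefficients are zeroed and the rest renormalized
#' to the simplex; the nu minimizing the RMSE between the reconstructed and
#' observed standardized mixture is selected. `engine = "nnls"` replaces the
#' SVR with non-negative least squares ([pracma::lsqnonneg()]), a
#' deterministic fallback.
#'
#' @param sample_expr Named numeric vector of one sample's expression.
#' @param sig Genes x cell-types signature matrix (row/col names required).
#' @param nus Candidate nu values (default 0.25, 0.5, 0.75).
#' @param engine "svr" (default) or "nnls".
#' @return A `deconv_result`: `fractions` (simplex over cell types),
#'   `nu_selected`, `pearson_r`, `rmse`.
#' @export
deconvolve <- function(sample_expr, sig, nus = c(0.25, 0.5, 0.75),
                       engine = c("svr", "nnls")) {
  engine <- match.arg(engine)
  shared <- intersect(names(sample_expr), rownames(sig))
  if (length(shared) < 30)
    stop("fewer than 30 genes shared between sample and signature")
  y <- as.numeric(scale(sample_expr[shared]))
  S <- apply(sig[shared, , drop = FALSE], 2, function(v) as.numeric(scale(v)))

  fit_one <- function(nu) {
    if (engine == "nnls") {
      w <- pracma::lsqnonneg(S, y)$x
    } else {
      fit <- e1071::svm(S, y, type = "nu-regression", kernel = "linear",
                        nu = nu, scale = FALSE)
      w <- as.numeric(t(fit$coefs) %*% fit$SV)
      w[w < 0] <- 0
    }
    if (all(w <= 0)) return(NULL)
    recon <- as.numeric(S %*% w)
    list(w = w, rmse = sqrt(mean((recon - y)^2)),
         r = stats::cor(recon, y))
  }
  fits <- if (engine == "nnls") list(fit_one(NA_real_)) else lapply(nus, fit_one)
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok)) stop("degenerate deconvolution: all coefficients <= 0")
  fits <- fits[ok]
  nus_ok <- if (engine == "nnls") NA_real_ else nus[ok]
  best <- which.min(vapply(fits, `[[`, numeric(1), "rmse"))
  w <- fits[[best]]$w
  structure(list(fractions = stats::setNames(w / sum(w), colnames(sig)),
                 nu_selected = nus_ok[best], pearson_r = fits[[best]]$r,
                 rmse = fits[[best]]$rmse),
            class = "deconv_result")
}

#' Deconvolve every sample of an expression matrix
#'
#' @param m An [expression_matrix()] (genes x samples).
#' @param sig Signature matrix (genes x cell types).
#' @param ... Passed to [deconvolve()].
#' @return List with `fractions` (samples x cell types matrix) and `fit`
#'   (data frame of per-sample nu, Pearson r, RMSE).
#' @export
deconvolve_cohort <- function(m, sig, ...) {
  x <- unclass(m)
  res <- lapply(colnames(x), function(s) deconvolve(x[, s], sig, ...))
  fractions <- do.call(rbind, lapply(res, `[[`, "fractions"))
  rownames(fractions) <- colnames(x)
  fit <- data.frame(sample_id = colnames(x),
                    nu_selected = vapply(res, `[[`, numeric(1), "nu_selected"),
                    pearson_r = vapply(res, `[[`, numeric(1), "pearson_r"),
                    rmse = vapply(res, `[[`, numeric(1), "rmse"),
                    stringsAsFactors = FALSE)
  list(fractions = fractions, fit = fit)
}

#' Associate cell-type fractions with the BASICq score
#'
#' Per cell type, a simple linear regression of fraction on BASICq; slopes,
#' R-squared, p-values and BH-adjusted p-values across cell types.
#'
#' @param fractions Samples x cell-types matrix.
#' @param basicq Numeric BASICq per sample (same order or named).
#' @return Data frame: `cell_type`, `slope`, `r_squared`, `p`, `adj_p`.
#' @export
fractions_vs_score <- function(fractions, basicq) {
  if (!is.null(names(basicq)) && !is.null(rownames(fractions)))
    basicq <- basicq[rownames(fractions)]
  if (length(basicq) != nrow(fractions))
    stop("basicq does not match the fraction matrix samples")
  rows <- lapply(colnames(fractions), function(ct) {
    y <- fractions[, ct]
    if (stats::var(y) == 0)
      return(data.frame(cell_type = ct, slope = 0, r_squared = 0, p = 1))
    fit <- stats::lm(y ~ basicq)
    sm <- summary(fit)
    data.frame(cell_type = ct, slope = unname(stats::coef(fit)[2]),
               r_squared = sm$r.squared,
               p = sm$coefficients[2, 4], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$adj_p <- bh_adjust(out$p)
  out
}
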
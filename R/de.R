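# Moderated two-group differential expression: per-gene pooled-variance
# linear models, empirical-Bayes variance shrinkage via moment matching of
# log residual variances to a scaled-F prior, BH adjustment, and the
# fold-change/significance flagging used for volcano displays.

#' Fit per-gene two-group linear models
#'
#' For each gene: log2 fold change = mean(group 1) - mean(group 2), pooled
#' residual variance with n - 2 degrees of freedom.
#'
#' @param m An [expression_matrix()] (genes x samples).
#' @param groups Labels (two levels) per sample; level "1" (or the first
#'   factor level) is the endotype-1 group.
#' @return Data frame: `gene`, `log2fc`, `s2`, `df`, plus attributes `n1`,
#'   `n2`.
#' @export
fit_gene_models <- function(m, groups) {
  x <- unclass(m)
  groups <- as.factor(groups)
  if (nlevels(groups) != 2) stop("exactly two groups are required")
  g1 <- groups == levels(groups)[1]
  n1 <- sum(g1); n2 <- sum(!g1)
  if (n1 < 2 || n2 < 2) stop("each group needs at least 2 samples")
  m1 <- rowMeans(x[, g1, drop = FALSE])
  m2 <- rowMeans(x[, !g1, drop = FALSE])
  ss1 <- rowSums((x[, g1, drop = FALSE] - m1)^2)
  ss2 <- rowSums((x[, !g1, drop = FALSE] - m2)^2)
  df <- n1 + n2 - 2
  out <- data.frame(gene = rownames(x), log2fc = m1 - m2,
                    s2 = (ss1 + ss2) / df, df = df,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "n1") <- n1
  attr(out, "n2") <- n2
  out
}

# Newton inversion of the trigamma function (solve trigamma(y) = x), the
# standard step of the log-variance moment-matching estimator.
trigamma_inverse <- function(x, tol = 1e-8, max_iter = 50L) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in seq_len(max_iter)) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2L)
    y <- y + dif
    if (abs(dif) < tol * y) break
  }
  y
}

#' Empirical-Bayes moderation of gene-wise variances
#'
#' Estimates the prior degrees of freedom d0 and prior variance s0^2 of a
#' scaled inverse-chi-square variance hierarchy by matching the first two
#' moments of log s_g^2 (digamma/trigamma inversion, Newton iterations at
#' tolerance 1e-8), then shrinks each gene's variance to the posterior
#' s~_g^2 = (d0 s0^2 + df s_g^2) / (d0 + df) and forms moderated
#' t-statistics with d0 + df degrees of freedom. When the moment estimate of
#' the prior df is non-finite (observed variances no more dispersed than
#' sampling noise), d0 = Inf and the common-variance t is used.
#'
#' @param fits Output of [fit_gene_models()].
#' @return A `moderated_stats` data frame: `gene`, `log2fc`, `s2`,
#'   `s2_post`, `t_mod`, `df_total`, `p`, `adj_p`; attributes `d0`, `s0_sq`.
#' @export
ebayes_moderate <- function(fits) {
  ok <- is.finite(fits$s2) & fits$s2 > 0
  if (sum(ok) < 10) stop("need at least 10 genes with positive variance")
  df <- fits$df[1]
  z <- log(fits$s2[ok])
  e <- z - digamma(df / 2) + log(df / 2)
  evar <- stats::var(e)
  tri_target <- evar - trigamma(df / 2)
  if (is.finite(tri_target) && tri_target > 0) {
    d0 <- 2 * trigamma_inverse(tri_target)
    s0_sq <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  } else {
    # variances no more dispersed than sampling noise: infinite prior df,
    # every gene shares the (geometric-mean-based) common variance
    d0 <- Inf
    s0_sq <- exp(mean(z))
  }
  s2_post <- if (is.finite(d0)) (d0 * s0_sq + fits$df * fits$s2) / (d0 + fits$df)
             else rep(s0_sq, nrow(fits))
  n1 <- attr(fits, "n1"); n2 <- attr(fits, "n2")
  se <- sqrt(s2_post * (1 / n1 + 1 / n2))
  t_mod <- fits$log2fc / se
  df_total <- d0 + fits$df
  p <- 2 * stats::pt(-abs(t_mod), df = if (is.finite(d0)) df_total else Inf)
  out <- data.frame(gene = fits$gene, log2fc = fits$log2fc, s2 = fits$s2,
                    s2_post = s2_post, t_mod = t_mod, df_total = df_total,
                    p = p, adj_p = bh_adjust(p), stringsAsFactors = FALSE)
  attr(out, "d0") <- d0
  attr(out, "s0_sq") <- s0_sq
  attr(out, "n1") <- n1
  attr(out, "n2") <- n2
  class(out) <- c("moderated_stats", "data.frame")
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Thin wrapper over [stats::p.adjust()] (method "BH") with input
#' validation: monotone step-up adjustment, capped at 1.
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @return Adjusted p-values, same order as input.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Flag differentially expressed genes for a volcano display
#'
#' Flags genes with |log2fc| >= `fc_threshold` AND adjusted p < `alpha`
#' (boundary semantics: fold change inclusive, significance exclusive).
#' Positive direction = up in endotype 1.
#'
#' @param stats A `moderated_stats` table.
#' @param fc_threshold Absolute log2 fold-change threshold (default 1.5).
#' @param alpha Adjusted-p threshold (default 0.05).
#' @return The table with `flagged` (logical) and `direction` (-1/0/+1)
#'   columns appended.
#' @export
volcano_table <- function(stats, fc_threshold = 1.5, alpha = 0.05) {
  out <- as.data.frame(stats)
  out$flagged <- abs(out$log2fc) >= fc_threshold & out$adj_p < alpha
  out$direction <- ifelse(out$flagged, sign(out$log2fc), 0)
  out
}
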
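# Preprocessing: cross-sample distribution alignment, probe collapsing,
# expressed-gene filtering, top-variance feature selection. Fixed order:
# normalize -> collapse -> filter -> select.

#' Quantile-normalize an expression matrix
#'
#' Aligns every sample column to the column-wise mean of the sorted inputs
#' (ties resolved by averaging), via [limma::normalizeQuantiles()]. This is
#' the standard cross-sample distribution alignment for array intensities.
#'
#' @param m An [expression_matrix()].
#' @return The normalized [expression_matrix()].
#' @export
quantile_normalize <- function(m) {
  stopifnot(inherits(m, "expression_matrix"))
  if (ncol(m) < 2) {
    warning("single sample: quantile normalization is a no-op")
    return(m)
  }
  out <- limma::normalizeQuantiles(unclass(m), ties = TRUE)
  expression_matrix(out, rownames(m), colnames(m), level = attr(m, "level"))
}

#' Collapse probe-level rows to gene level by mean
#'
#' Each gene's expression is the arithmetic mean of its probes; probes absent
#' from the mapping are dropped and counted.
#'
#' @param m A probe-level [expression_matrix()].
#' @param probe2gene Named character vector mapping probe id -> gene id.
#' @return List with `matrix` (gene-level [expression_matrix()]) and
#'   `n_unmapped` (dropped probe count).
#' @export
collapse_probes <- function(m, probe2gene) {
  stopifnot(inherits(m, "expression_matrix"))
  if (attr(m, "level") != "probe")
    stop("collapse_probes expects a probe-level matrix")
  if (length(probe2gene) == 0) stop("empty probe-to-gene mapping")
  mapped <- rownames(m) %in% names(probe2gene)
  n_unmapped <- sum(!mapped)
  if (!any(mapped)) stop("no probes map to any gene")
  sub <- m[mapped, , drop = FALSE]
  genes <- probe2gene[rownames(sub)]
  collapsed <- rowsum(unclass(sub), group = genes, reorder = TRUE)
  counts <- as.vector(table(genes)[rownames(collapsed)])
  collapsed <- collapsed / counts
  list(matrix = expression_matrix(collapsed, rownames(collapsed), colnames(m),
                                  level = "gene"),
       n_unmapped = n_unmapped)
}

#' Remove genes with zero expression status
#'
#' A row is removed when its value is at or below `floor` (log2 scale,
#' default 0 = the linear-scale zero) in all samples (`all_samples = TRUE`,
#' the default) or in any sample.
#'
#' @param m An [expression_matrix()].
#' @param floor Expression floor on the log2 scale.
#' @param all_samples If TRUE a row must be at/below floor in every sample to
#'   be removed; if FALSE, in at least one.
#' @return List with `matrix` and `report` (a `preprocess_report` with in/out
#'   and removal counts).
#' @export
filter_expressed <- function(m, floor = 0, all_samples = TRUE) {
  stopifnot(inherits(m, "expression_matrix"))
  at_floor <- unclass(m) <= floor
  remove <- if (all_samples) rowSums(at_floor) == ncol(m)
            else rowSums(at_floor) > 0
  if (all(remove)) stop("all rows removed by expression filter")
  out <- expression_matrix(unclass(m)[!remove, , drop = FALSE],
                           rownames(m)[!remove], colnames(m),
                           level = attr(m, "level"))
  report <- structure(list(n_probes_in = nrow(m), n_zero_filtered = sum(remove),
                           n_genes_out = nrow(out), variance_quantile = NA_real_,
                           n_features_selected = NA_integer_),
                      class = "preprocess_report")
  list(matrix = out, report = report)
}

#' Keep the top fraction of genes by sample variance
#'
#' Retains the `ceiling(q * G)` rows with largest variance across samples,
#' with a deterministic lexicographic tie-break on gene id at the cut.
#'
#' @param m An [expression_matrix()].
#' @param q Fraction in (0, 1] of rows to keep (default 0.15, the top-15%
#'   most variable genes).
#' @return The reduced [expression_matrix()].
#' @export
top_variance_features <- function(m, q = 0.15) {
  stopifnot(inherits(m, "expression_matrix"))
  if (!is.numeric(q) || length(q) != 1 || q <= 0 || q > 1)
    stop("q must lie in (0, 1]")
  G <- nrow(m)
  keep_n <- ceiling(q * G)
  v <- apply(unclass(m), 1, stats::var)
  ord <- order(-v, rownames(m), method = "radix")
  keep <- sort(ord[seq_len(keep_n)])
  expression_matrix(unclass(m)[keep, , drop = FALSE], rownames(m)[keep],
                    colnames(m), level = attr(m, "level"))
}

#' Run the fixed preprocessing chain
#'
#' normalize -> (collapse if probe-level mapping given) -> filter -> select.
#'
#' @param m An [expression_matrix()].
#' @param probe2gene Optional probe-to-gene mapping for probe-level input.
#' @param floor Expression floor passed to [filter_expressed()].
#' @param top_frac Variance-selection fraction passed to
#'   [top_variance_features()].
#' @return List with `features` (selected matrix), `genes` (full filtered
#'   gene-level matrix, for differential expression) and `report`.
#' @export
preprocess_pipeline <- function(m, probe2gene = NULL, floor = 0,
                                top_frac = 0.15) {
  n_in <- nrow(m)
  m <- quantile_normalize(m)
  n_unmapped <- 0L
  if (attr(m, "level") == "probe") {
    if (is.null(probe2gene)) stop("probe-level input requires probe2gene")
    cp <- collapse_probes(m, probe2gene)
    m <- cp$matrix
    n_unmapped <- cp$n_unmapped
  }
  fl <- filter_expressed(m, floor = floor)
  feats <- top_variance_features(fl$matrix, q = top_frac)
  report <- structure(list(n_probes_in = n_in,
                           n_unmapped = n_unmapped,
                           n_zero_filtered = fl$report$n_zero_filtered,
                           n_genes_out = nrow(fl$matrix),
                           variance_quantile = top_frac,
                           n_features_selected = nrow(feats),
                           normalization = "quantile"),
                      class = "preprocess_report")
  list(features = feats, genes = fl$matrix, report = report)
}

#' @export
print.preprocess_report <- function(x, ...) {
  cat("preprocess_report:\n")
  for (nm in names(x)) cat(sprintf("  %s: %s\n", nm, format(x[[nm]])))
  invisible(x)
}
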
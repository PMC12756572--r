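# Controlled vocabularies for the clinical table. Reference levels (first
# element) match the baseline rows of the adjusted regression models:
# female, 0 to <1 month, infection/sepsis, no comorbidity, non-infectious.
CLINICAL_VOCAB <- list(
  sex = c("female", "male"),
  age_group = c("0 to <1 month", "1-11 months", "12-23 months",
                "24 months-4 years", "5-12 years", ">12 years"),
  admission_reason = c("infection/sepsis", "respiratory/airway", "neurological",
                       "cardiac", "trauma/head injury", "endocrine/metabolic",
                       "other"),
  comorbidity = c("none", "cardiac", "respiratory", "neurological",
                  "endocrine/metabolic", "hematology/oncology", "genetic",
                  "multi-system", "other"),
  infection_status = c("non-infectious", "unknown", "viral", "bacterial"),
  pards = c("none", "mild/moderate", "severe")
)

#' Construct a validated expression matrix
#'
#' Log2-scale expression values with gene (or probe) identifiers in rows and
#' sample identifiers in columns.
#'
#' @param values Numeric matrix, genes x samples, log2 intensity units.
#' @param gene_ids Character vector of row identifiers.
#' @param sample_ids Character vector of column identifiers.
#' @param level Either "gene" or "probe".
#' @return An object of class `expression_matrix`: the numeric matrix with
#'   dimnames set and a `level` attribute.
#' @export
expression_matrix <- function(values, gene_ids = rownames(values),
                              sample_ids = colnames(values),
                              level = c("gene", "probe")) {
  level <- match.arg(level)
  values <- as.matrix(values)
  if (is.null(gene_ids) || is.null(sample_ids))
    stop("gene_ids and sample_ids are required")
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  if (nrow(values) != length(gene_ids) || ncol(values) != length(sample_ids))
    stop("dimensions of values do not match identifier lists")
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (anyDuplicated(gene_ids))
    stop("duplicate gene ids: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  if (!all(is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1, ]
    stop(sprintf("non-finite expression value at gene '%s', sample '%s'",
                 gene_ids[bad[1]], sample_ids[bad[2]]))
  }
  dimnames(values) <- list(gene_ids, sample_ids)
  structure(values, level = level, class = c("expression_matrix", "matrix", "array"))
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d %ss x %d samples (log2 scale)\n",
              nrow(x), attr(x, "level"), ncol(x)))
  invisible(x)
}

#' Read an expression matrix from tab-separated text
#'
#' First column holds gene identifiers, the header row holds sample
#' identifiers. Cells must be finite numbers; `NA`, `NaN` or `Inf` cells are
#' rejected with the offending gene and sample named.
#'
#' @param path Path to a TSV file.
#' @param level "gene" or "probe"; recorded on the returned object.
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path, level = c("gene", "probe")) {
  level <- match.arg(level)
  lines <- readLines(path)
  if (length(lines) < 2L) stop("expression file has no data rows: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  widths <- lengths(fields)
  if (length(unique(widths)) != 1L)
    stop(sprintf("ragged expression file '%s': rows have %s fields",
                 path, paste(unique(widths), collapse = "/")))
  header <- fields[[1]]
  sample_ids <- header[-1]
  if (anyDuplicated(sample_ids))
    stop("duplicate sample id in header: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  body <- fields[-1]
  gene_ids <- vapply(body, `[[`, character(1), 1L)
  raw <- vapply(body, function(f) f[-1], character(length(sample_ids)))
  raw <- if (is.null(dim(raw))) matrix(raw, nrow = 1L) else t(raw)
  vals <- suppressWarnings(matrix(as.numeric(raw), nrow = nrow(raw)))
  if (anyNA(vals) || !all(is.finite(vals))) {
    bad <- which(is.na(vals) | !is.finite(vals), arr.ind = TRUE)[1, ]
    stop(sprintf(
      "non-numeric or non-finite cell '%s' at gene '%s', sample '%s' in %s",
      raw[bad[1], bad[2]], gene_ids[bad[1]], sample_ids[bad[2]], path))
  }
  expression_matrix(vals, gene_ids, sample_ids, level = level)
}

#' Write an expression matrix as tab-separated text
#'
#' Numeric cells are serialized at 6 significant digits, sufficient for
#' bit-stable round-tripping of every downstream statistic.
#'
#' @param m An [expression_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(m, path) {
  header <- paste(c("gene_id", colnames(m)), collapse = "\t")
  rows <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(rownames(m)[i], formatC(m[i, ], format = "g", digits = 6)),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read a gene-set collection in GMT format
#'
#' Standard GMT dialect: one set per line, `name TAB description TAB gene...`.
#' Duplicate genes within a set are dropped with a warning; set order is
#' preserved.
#'
#' @param path Path to a GMT file.
#' @return A `gene_set_collection`: list with `sets` (named list of character
#'   vectors), `descriptions` (named character) and `n_duplicates_dropped`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list(); desc <- character(0); ndup <- 0L
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L)
      stop("GMT line with fewer than 3 fields: ", substr(ln, 1, 60))
    genes <- f[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (anyDuplicated(genes)) {
      k <- sum(duplicated(genes))
      ndup <- ndup + k
      warning(sprintf("set '%s': dropped %d duplicate gene(s)", f[1], k))
      genes <- unique(genes)
    }
    if (length(genes) == 0L)
      stop("empty gene set: ", f[1])
    sets[[f[1]]] <- genes
    desc[f[1]] <- f[2]
  }
  structure(list(sets = sets, descriptions = desc,
                 n_duplicates_dropped = ndup),
            class = "gene_set_collection")
}

#' Write a gene-set collection in GMT format
#' @param gsc A `gene_set_collection` (or plain named list of gene vectors).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(gsc, path) {
  sets <- if (inherits(gsc, "gene_set_collection")) gsc$sets else gsc
  desc <- if (inherits(gsc, "gene_set_collection")) gsc$descriptions else
    setNames(rep("na", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, desc[[nm]], sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection: %d sets (sizes %s)\n", length(x$sets),
              paste(range(lengths(x$sets)), collapse = "-")))
  invisible(x)
}

validate_clinical <- function(df) {
  required <- c("sample_id", "sex", "age_group", "admission_reason",
                "comorbidity", "infection_status", "pim2",
                "ventilation_days", "died_by_day30", "vasoactive")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("clinical table missing required columns: ",
         paste(missing, collapse = ", "))
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  for (col in c("sex", "age_group", "admission_reason", "comorbidity",
                "infection_status")) {
    vocab <- CLINICAL_VOCAB[[col]]
    vals <- as.character(df[[col]])
    bad <- setdiff(unique(vals), vocab)
    if (length(bad))
      stop(sprintf("invalid %s value(s) %s; allowed values: %s", col,
                   paste(sQuote(bad), collapse = ", "),
                   paste(sQuote(vocab), collapse = ", ")))
    df[[col]] <- factor(vals, levels = vocab)
  }
  if ("pards" %in% names(df)) {
    vals <- as.character(df$pards)
    bad <- setdiff(unique(vals[!is.na(vals)]), CLINICAL_VOCAB$pards)
    if (length(bad))
      stop(sprintf("invalid pards value(s) %s; allowed values: %s",
                   paste(sQuote(bad), collapse = ", "),
                   paste(sQuote(CLINICAL_VOCAB$pards), collapse = ", ")))
    df$pards <- factor(vals, levels = CLINICAL_VOCAB$pards)
  }
  df$pim2 <- as.numeric(df$pim2)
  if (any(!is.finite(df$pim2)) || any(df$pim2 <= 0 | df$pim2 >= 1))
    stop("pim2 must lie strictly in (0, 1)")
  df$ventilation_days <- as.integer(df$ventilation_days)
  if (any(is.na(df$ventilation_days)) || any(df$ventilation_days < 0))
    stop("ventilation_days must be a non-negative integer")
  df$died_by_day30 <- as.logical(df$died_by_day30)
  df$vasoactive <- as.logical(df$vasoactive)
  if (anyNA(df$died_by_day30) || anyNA(df$vasoactive))
    stop("died_by_day30 and vasoactive must be logical with no missing values")
  class(df) <- c("clinical_table", "data.frame")
  df
}

#' Read and validate a per-sample clinical table
#'
#' Comma-separated text with one row per sample. Categorical columns are
#' validated against controlled vocabularies (see `endokit:::CLINICAL_VOCAB`);
#' unknown extra columns are carried through untouched.
#'
#' @param path Path to a CSV file.
#' @return A `clinical_table` data frame with factor-encoded categories.
#' @export
read_clinical <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  validate_clinical(df)
}

#' Write a clinical table as CSV
#' @param df A `clinical_table` (or compatible data frame).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clinical <- function(df, path) {
  out <- as.data.frame(df)
  num <- vapply(out, is.double, logical(1))
  out[num] <- lapply(out[num], signif, digits = 6)
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Write a set of result tables plus a JSON manifest
#'
#' Each table is written as `<name>.csv` under `out_dir`; the manifest
#' (`manifest.json`) lists every emitted file with its row count.
#'
#' @param tables Named list of data frames.
#' @param out_dir Output directory, created if absent.
#' @return The manifest, invisibly (named list of file -> row count).
#' @export
write_results <- function(tables, out_dir) {
  stopifnot(is.list(tables), !is.null(names(tables)), all(nzchar(names(tables))))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- lapply(names(tables), function(nm) {
    f <- file.path(out_dir, paste0(nm, ".csv"))
    df <- as.data.frame(tables[[nm]])
    num <- vapply(df, is.double, logical(1))
    df[num] <- lapply(df[num], signif, digits = 6)
    utils::write.csv(df, f, row.names = FALSE, quote = TRUE)
    list(file = basename(f), n_rows = nrow(df))
  })
  names(manifest) <- names(tables)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
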
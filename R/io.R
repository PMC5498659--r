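#' Construct an expression matrix container
#'
#' Bundles a genes-by-samples numeric matrix with the tumor/reference label of
#' each sample. Reference (normal) samples define the normalization baseline
#' and the starting point of each process's principal curve.
#'
#' @param values numeric matrix, genes in rows, samples in columns; both
#'   dimensions must carry unique names.
#' @param reference character vector of sample ids to flag as reference
#'   (normal) samples. May be empty (all samples treated as tumor).
#' @return An object of class `expr_matrix`: a list with elements `values`
#'   (the matrix) and `is_reference` (named logical over samples).
#' @examples
#' m <- matrix(rnorm(6), 2, 3,
#'             dimnames = list(c("g1", "g2"), c("s1", "s2", "n1")))
#' expression_matrix(m, reference = "n1")
#' @export
expression_matrix <- function(values, reference = character()) {
  if (!is.matrix(values) || !is.numeric(values))
    abort_argument("`values` must be a numeric matrix")
  gene_ids <- rownames(values)
  sample_ids <- colnames(values)
  if (is.null(gene_ids) || is.null(sample_ids))
    abort_argument("`values` must have row (gene) and column (sample) names")
  if (anyDuplicated(gene_ids))
    abort_format(sprintf("duplicate gene id(s): %s",
                         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", ")))
  if (anyDuplicated(sample_ids))
    abort_format("duplicate sample ids")
  missing_ref <- setdiff(reference, sample_ids)
  if (length(missing_ref))
    abort_argument(sprintf("reference id(s) absent from samples: %s",
                           paste(missing_ref, collapse = ", ")))
  structure(
    list(values = values,
         is_reference = setNames(sample_ids %in% reference, sample_ids)),
    class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expression matrix: %d genes x %d samples (%d reference)\n",
              nrow(x$values), ncol(x$values), sum(x$is_reference)))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Construct a gene set collection
#'
#' @param sets named list of character vectors (set name -> gene symbols).
#' @param description optional character vector of set descriptions, recycled
#'   or named like `sets`.
#' @return An object of class `gene_sets`: the named list with a
#'   `description` attribute.
#' @export
gene_sets <- function(sets, description = NULL) {
  if (length(sets) && is.null(names(sets)))
    abort_argument("gene sets must be named")
  if (anyDuplicated(names(sets)))
    abort_format("duplicate gene set names")
  if (any(!lengths(sets)))
    abort_format("every gene set must be non-empty")
  sets <- lapply(sets, function(g) unique(as.character(g)))
  if (is.null(description)) description <- rep("", length(sets))
  structure(sets, description = setNames(rep_len(description, length(sets)),
                                         names(sets)),
            class = "gene_sets")
}

#' @export
print.gene_sets <- function(x, ...) {
  cat(sprintf("gene set collection: %d sets", length(x)))
  if (length(x))
    cat(sprintf(" (sizes %d-%d)", min(lengths(x)), max(lengths(x))))
  cat("\n")
  invisible(x)
}

#' Read a GMT gene set file
#'
#' Broad-dialect GMT: one set per line, tab-separated fields
#' `name`, `description`, then gene symbols. Duplicate genes within a set are
#' dropped keeping the first occurrence.
#'
#' @param path path to a GMT file.
#' @return A [gene_sets] collection (empty file gives an empty collection).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) abort_argument(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  if (!length(lines)) return(gene_sets(setNames(list(), character())))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad))
    abort_format(sprintf("GMT line %d has fewer than 3 tab-separated fields",
                         which(keep)[bad[1]]))
  nms <- vapply(fields, `[[`, "", 1L)
  dup <- which(duplicated(nms))
  if (length(dup))
    abort_format(sprintf("duplicate gene set name '%s' at GMT line %d",
                         nms[dup[1]], which(keep)[dup[1]]))
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  desc <- vapply(fields, `[[`, "", 2L)
  gene_sets(setNames(sets, nms), description = desc)
}

#' Write a gene set collection to a GMT file
#'
#' @param sets a [gene_sets] collection.
#' @param path output path.
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "description") %||% rep("", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], desc[[i]], sets[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a tab-separated expression matrix
#'
#' Expects a header row of sample ids and a first column of gene symbols.
#' Genes with any missing value are dropped (the downstream scoring is
#' variance-sensitive; imputation would silently distort it) and the count is
#' reported via `message()`.
#'
#' @param path path to the TSV file.
#' @param reference_ids sample ids to flag as reference (normal) samples;
#'   every id must appear in the header.
#' @return An [expression_matrix].
#' @export
read_expression <- function(path, reference_ids = character()) {
  if (!file.exists(path)) abort_argument(sprintf("file not found: %s", path))
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) abort_format("expression table needs a gene column and >= 1 sample")
  genes <- as.character(tab[[1L]])
  if (anyDuplicated(genes))
    abort_format(sprintf("duplicate gene id(s): %s",
                         paste(unique(genes[duplicated(genes)]), collapse = ", ")))
  values <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(values) <- "double"
  rownames(values) <- genes
  incomplete <- apply(values, 1L, anyNA)
  if (any(incomplete)) {
    message(sprintf("dropped %d gene(s) with missing values", sum(incomplete)))
    values <- values[!incomplete, , drop = FALSE]
  }
  expression_matrix(values, reference = reference_ids)
}

#' Write an expression matrix as TSV
#'
#' @param expr an [expression_matrix].
#' @param path output path.
#' @export
write_expression <- function(expr, path) {
  df <- data.frame(gene = rownames(expr$values), expr$values,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a clinical table
#'
#' Requires columns `sample`, `time` (positive follow-up time) and `status`
#' (event indicator, 0/1); any further columns are kept as categorical
#' covariates.
#'
#' @param path path to the TSV file.
#' @return A data.frame with at least `sample`, `time`, `status`.
#' @export
read_clinical <- function(path) {
  if (!file.exists(path)) abort_argument(sprintf("file not found: %s", path))
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("sample", "time", "status")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    abort_format(sprintf("clinical table missing column(s): %s",
                         paste(miss, collapse = ", ")))
  if (any(!is.finite(tab$time)) || any(tab$time <= 0))
    abort_format("clinical `time` must be positive and finite")
  if (!all(tab$status %in% c(0, 1)))
    abort_format("clinical `status` must be 0/1")
  tab$sample <- as.character(tab$sample)
  extra <- setdiff(names(tab), need)
  for (v in extra) tab[[v]] <- factor(tab[[v]])
  tab
}

#' Write a BPS matrix as TSV
#'
#' Rows are processes, columns samples, values printed with 6 decimal places
#' so a read-back reproduces the matrix within 1e-6.
#'
#' @param bps a `bps` object from [bps_score()] or a numeric matrix
#'   (processes x samples) with dimnames.
#' @param path output path.
#' @export
write_bps <- function(bps, path) {
  values <- if (inherits(bps, "bps")) bps$values else bps
  if (!is.matrix(values)) abort_argument("`bps` must be a matrix or bps object")
  if (length(values) && any(!is.finite(values)))
    abort_argument("BPS values must be finite")
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste(c("process", colnames(values)), collapse = "\t"), con)
  if (nrow(values)) {
    body <- apply(values, 1L, function(v)
      paste(formatC(v, digits = 6, format = "f"), collapse = "\t"))
    writeLines(paste(rownames(values), body, sep = if (ncol(values)) "\t" else ""),
               con)
  }
  invisible(path)
}

#' Read a BPS matrix written by [write_bps()]
#'
#' @param path path to the TSV file.
#' @return Numeric matrix, processes in rows, samples in columns.
#' @export
read_bps <- function(path) {
  if (!file.exists(path)) abort_argument(sprintf("file not found: %s", path))
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(tab[[1L]])
  m
}
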
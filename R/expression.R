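#' Construct an expression matrix
#'
#' A thin validated container for a genes-by-samples real matrix carrying a
#' condition label.  Row names are gene identifiers, column names sample
#' identifiers.
#'
#' @param values numeric matrix, genes in rows, samples in columns; must have
#'   unique row names and contain only finite values.
#' @param condition one of `"case"`, `"control"`, `"unlabeled"`.
#' @return an object of class `expr_matrix`: a list with elements `values`,
#'   `gene_ids`, `sample_ids`, `condition`.
#' @export
expression_matrix <- function(values, condition = c("unlabeled", "case", "control")) {
  condition <- match.arg(condition)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)))
    rownames(values) <- paste0("G", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- paste0("S", seq_len(ncol(values)))
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene identifiers: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (!all(is.finite(values)))
    stop("expression values must be finite (no NA/NaN/Inf)")
  structure(list(values = values,
                 gene_ids = rownames(values),
                 sample_ids = colnames(values),
                 condition = condition),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d samples (condition: %s)\n",
              nrow(x$values), ncol(x$values), x$condition))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

n_samples <- function(m) ncol(m$values)

#' Load a gene-by-sample expression table
#'
#' Reads a tab-separated file whose first column holds gene identifiers and
#' whose header row holds sample identifiers.  Every data cell must parse as a
#' finite number; the first offending cell is reported by gene and sample.
#'
#' @param path path to a TSV file.
#' @param condition condition label to attach, see [expression_matrix()].
#' @return an [expression_matrix()].
#' @export
load_expression_table <- function(path, condition = "unlabeled") {
  if (!file.exists(path)) stop("expression file not found: ", path)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE)
  if (ncol(raw) < 2) stop("expression table needs a gene column plus >=1 sample column: ", path)
  genes <- trimws(raw[[1]])
  if (anyDuplicated(genes))
    stop("duplicate gene identifier(s) in ", path, ": ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  samples <- colnames(raw)[-1]
  vals <- suppressWarnings(
    vapply(raw[-1], function(col) as.numeric(col), numeric(nrow(raw))))
  vals <- matrix(vals, nrow = nrow(raw), dimnames = list(genes, samples))
  bad <- which(!is.finite(vals), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    i <- bad[1, 1]; j <- bad[1, 2]
    stop(sprintf("non-numeric value '%s' at gene '%s', sample '%s' in %s",
                 raw[i, j + 1L], genes[i], samples[j], path))
  }
  expression_matrix(vals, condition = condition)
}

#' Write an expression matrix as TSV
#'
#' Inverse of [load_expression_table()]; first column is named `gene`.
#'
#' @param m an `expr_matrix`.
#' @param path output path.
#' @export
write_expression_table <- function(m, path) {
  stopifnot(inherits(m, "expr_matrix"))
  df <- data.frame(gene = m$gene_ids, m$values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Load a gene list (one identifier per line)
#'
#' Lines starting with `#` and blank lines are ignored; surrounding whitespace
#' is stripped.  Used for candidate-regulator lists and gene sets.
#'
#' @param path path to a plain-text file.
#' @return character vector of identifiers (duplicates dropped with a warning).
#' @export
load_gene_list <- function(path) {
  if (!file.exists(path)) stop("gene list file not found: ", path)
  x <- trimws(readLines(path, warn = FALSE))
  x <- x[nzchar(x) & !startsWith(x, "#")]
  if (anyDuplicated(x)) {
    warning("duplicate identifiers in ", path, "; keeping first occurrence")
    x <- x[!duplicated(x)]
  }
  x
}

# Validate a candidate-regulator set against an expression matrix.
check_regulators <- function(regs, m) {
  if (length(regs) == 0) stop("regulator list is empty")
  missing <- setdiff(regs, m$gene_ids)
  if (length(missing) > 0)
    stop("regulator(s) absent from expression matrix: ",
         paste(utils::head(missing, 5), collapse = ", "),
         if (length(missing) > 5) sprintf(" (and %d more)", length(missing) - 5))
  invisible(regs)
}

#' Standardize each gene to mean zero and unit population standard deviation
#'
#' Each row is centered and scaled by its population (denominator-`n`)
#' standard deviation, so that `mean(row^2) == 1` exactly afterwards.  With
#' this convention the prediction error of an all-zero weight vector is
#' exactly 1, which pins the no-signal DISCERN score at 1.
#'
#' @param m an `expr_matrix`.
#' @return the standardized `expr_matrix` (same condition label).
#' @export
standardize_by_gene <- function(m) {
  stopifnot(inherits(m, "expr_matrix"))
  v <- m$values
  n <- ncol(v)
  mu <- rowMeans(v)
  sdp <- sqrt(rowMeans((v - mu)^2))
  zero <- sdp <= 0
  if (any(zero))
    stop("constant gene row(s), cannot standardize: ",
         paste(m$gene_ids[zero], collapse = ", "))
  out <- (v - mu) / sdp
  expression_matrix(out, condition = m$condition)
}

#' Restrict two expression matrices to their shared genes
#'
#' Both matrices are subset to the intersection of their gene identifiers, in
#' the order the genes appear in `a`.  Genes measured in only one condition
#' are dropped.
#'
#' @param a,b `expr_matrix` objects.
#' @return list with elements `a` and `b`, row-aligned.
#' @export
align_conditions <- function(a, b) {
  stopifnot(inherits(a, "expr_matrix"), inherits(b, "expr_matrix"))
  common <- intersect(a$gene_ids, b$gene_ids)
  if (length(common) == 0) stop("the two matrices share no gene identifiers")
  list(a = expression_matrix(a$values[common, , drop = FALSE], a$condition),
       b = expression_matrix(b$values[common, , drop = FALSE], b$condition))
}

#' Write a score table as TSV
#'
#' Columns: gene, discern, d0, lns, dscore, anova, pvalue, qvalue.
#'
#' @param st a `score_table` data frame from [score_all()].
#' @param path output path.
#' @export
write_score_table <- function(st, path) {
  stopifnot(is.data.frame(st))
  utils::write.table(st, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a score table written by [write_score_table()]
#' @param path TSV path.
#' @return data frame of class `score_table`.
#' @export
read_score_table <- function(path) {
  st <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  class(st) <- c("score_table", "data.frame")
  st
}
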
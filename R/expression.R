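#' Expression matrix with sample design labels
#'
#' Container for a genes x samples matrix of (log-scale) expression values
#' plus the experimental design of each sample column: genotype (OE, RE, WT),
#' condition (control, drought) and replicate number. Sample ids are
#' `genotype_condition_rep`.
#'
#' @param values numeric matrix, rownames = gene ids, colnames = sample ids.
#' @param samples data.frame with columns `sample`, `genotype`, `condition`,
#'   `replicate`, one row per column of `values` and in the same order.
#' @return an object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, samples) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (anyNA(values)) stop("expression values must not contain missing values")
  if (is.null(rownames(values))) stop("values must have gene ids as rownames")
  if (anyDuplicated(rownames(values))) {
    stop("duplicate gene id: ",
         rownames(values)[anyDuplicated(rownames(values))])
  }
  stopifnot(is.data.frame(samples),
            all(c("sample", "genotype", "condition", "replicate")
                %in% names(samples)),
            nrow(samples) == ncol(values))
  if (!identical(colnames(values), samples$sample)) {
    colnames(values) <- samples$sample
  }
  structure(list(values = values, samples = samples),
            class = "expression_matrix")
}

#' Extract the numeric value matrix of an expression object
#' @param expr an [expression_matrix] (a plain matrix passes through).
#' @return numeric genes x samples matrix.
#' @export
expr_values <- function(expr) {
  if (inherits(expr, "expression_matrix")) expr$values
  else if (is.matrix(expr)) expr
  else stop("not an expression_matrix")
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d samples\n",
              nrow(x$values), ncol(x$values)))
  tab <- table(x$samples$genotype, x$samples$condition)
  cat("samples per genotype x condition:\n")
  print(tab)
  invisible(x)
}

#' Select sample ids by design labels
#'
#' @param expr an [expression_matrix].
#' @param genotype,condition optional label filters (character vectors).
#' @return character vector of matching sample ids.
#' @export
samples_where <- function(expr, genotype = NULL, condition = NULL) {
  s <- expr$samples
  keep <- rep(TRUE, nrow(s))
  if (!is.null(genotype)) keep <- keep & s$genotype %in% genotype
  if (!is.null(condition)) keep <- keep & s$condition %in% condition
  s$sample[keep]
}
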
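#' Per-gene two-group differential test (Welch's t on log2 values)
#'
#' A plumbing-level stand-in for a dedicated count-based DE method, so that
#' synthetic data can flow through the DEG filter end to end: per gene, a
#' Welch two-sample t-test on the (log2-scale) expression values of the two
#' groups, with `log2_fold_change = mean(a) - mean(b)` and BH adjustment
#' across all genes in the table. Real DE result tables can be supplied to
#' [filter_degs()] directly, bypassing this function.
#'
#' Zero-variance conventions: identical distributions with zero mean
#' difference give p = 1; zero variance with a nonzero difference gives p = 0
#' with a warning.
#'
#' @param expr an [expression_matrix] of log2-scale values.
#' @param group_a,group_b disjoint character vectors of sample ids, each of
#'   size >= 2.
#' @return data.frame with columns `gene`, `log2fc`, `pvalue`, `fdr`.
#' @export
test_differential <- function(expr, group_a, group_b) {
  v <- expr_values(expr)
  group_a <- as.character(group_a); group_b <- as.character(group_b)
  if (length(intersect(group_a, group_b))) stop("groups must be disjoint")
  if (length(group_a) < 2 || length(group_b) < 2) {
    stop("each group needs at least 2 samples")
  }
  missing <- setdiff(c(group_a, group_b), colnames(v))
  if (length(missing)) stop("unknown sample id(s): ",
                            paste(utils::head(missing, 5), collapse = ", "))
  a <- v[, group_a, drop = FALSE]
  b <- v[, group_b, drop = FALSE]
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- apply(a, 1, stats::var); vb <- apply(b, 1, stats::var)
  lfc <- ma - mb
  se2 <- va / na + vb / nb
  p <- numeric(nrow(v))
  degenerate <- se2 == 0
  if (any(degenerate & lfc != 0)) {
    warning(sum(degenerate & lfc != 0),
            " zero-variance gene(s) with nonzero difference: p set to 0")
  }
  p[degenerate] <- ifelse(lfc[degenerate] == 0, 1, 0)
  if (any(!degenerate)) {
    i <- !degenerate
    tstat <- lfc[i] / sqrt(se2[i])
    df <- se2[i]^2 / ((va[i] / na)^2 / (na - 1) + (vb[i] / nb)^2 / (nb - 1))
    p[i] <- 2 * stats::pt(-abs(tstat), df = df)
  }
  data.frame(gene = rownames(v), log2fc = lfc, pvalue = p,
             fdr = stats::p.adjust(p, method = "BH"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Filter a DE result table to differentially expressed genes
#'
#' A gene is a DEG when `fdr < fdr_max` (strict, per the printed "FDR < 0.05")
#' and `|log2fc| >= log2(min_fold)` (inclusive, per "absolute fold change
#' >= 2"). Labels are `up` for positive and `down` for negative log2 fold
#' change.
#'
#' @param rows data.frame with columns `gene`, `log2fc`, `fdr` (e.g. from
#'   [test_differential()] or an external DE table).
#' @param fdr_max exclusive FDR threshold (default 0.05).
#' @param min_fold minimum absolute linear fold change, >= 1 (default 2).
#' @return list: `degs` (data.frame `gene`, `log2fc`, `fdr`, `direction`),
#'   `n_total`, `n_up`, `n_down` (always `n_total = n_up + n_down`).
#' @export
filter_degs <- function(rows, fdr_max = 0.05, min_fold = 2) {
  stopifnot(is.data.frame(rows),
            all(c("gene", "log2fc", "fdr") %in% names(rows)),
            min_fold >= 1)
  keep <- rows$fdr < fdr_max & abs(rows$log2fc) >= log2(min_fold)
  degs <- rows[keep, c("gene", "log2fc", "fdr"), drop = FALSE]
  degs$direction <- ifelse(degs$log2fc > 0, "up", "down")
  rownames(degs) <- NULL
  list(degs = degs, n_total = nrow(degs),
       n_up = sum(degs$direction == "up"),
       n_down = sum(degs$direction == "down"))
}

#' Intersect DEG sets across comparisons
#'
#' @param sets list of at least two character vectors of gene ids.
#' @return character vector: genes present in every set (sorted).
#' @export
#' @examples
#' intersect_deg_sets(list(c("a", "b", "c"), c("b", "c", "d")))
intersect_deg_sets <- function(sets) {
  stopifnot(is.list(sets), length(sets) >= 2)
  sort(Reduce(intersect, sets))
}
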
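#' Pearson correlation with a t-based significance test
#'
#' Computes the sample Pearson correlation between two expression profiles and
#' a two-sided p-value from the exact t statistic
#' `r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom. Perfect
#' collinearity (`r = +/-1`) returns `p = 0`.
#'
#' @param x,y numeric vectors of equal length `n >= 3`; neither may be
#'   constant (a constant profile has no defined correlation and is an error,
#'   not an `NA`).
#' @return a list of class `correlation_result` with fields `r`, `p_value`, `n`.
#' @export
#' @examples
#' pearson_cc(c(1, 2, 3), c(2, 4, 6))$r   # 1
pearson_cc <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3) stop("need at least 3 paired observations")
  if (anyNA(x) || anyNA(y)) stop("missing values are not allowed")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined: at least one input vector is constant")
  }
  r <- stats::cor(x, y)
  p <- .cor_pvalue(r, n)
  structure(list(r = r, p_value = p, n = n), class = "correlation_result")
}

# two-sided p for a Pearson r at sample size n; r^2 >= 1 maps to p = 0
.cor_pvalue <- function(r, n) {
  denom <- 1 - r^2
  p <- ifelse(denom <= 0, 0,
              2 * stats::pt(-abs(r * sqrt((n - 2) / pmax(denom, 0))), df = n - 2))
  pmin(p, 1)
}

#' Detect coexpressed gene pairs
#'
#' All unordered pairs among `genes` whose Pearson correlation across samples
#' passes the coexpression gate: `|r| >= cc_min` (or `r >= cc_min` when
#' `signed_cc`) and `p < p_max` (strict). Pairs are returned with
#' `gene_x < gene_y` lexicographically and sorted the same way, so output
#' order is deterministic.
#'
#' @param expr an [expression_matrix].
#' @param genes character vector of candidate gene ids (default: all genes).
#' @param cc_min inclusive correlation threshold (default 0.8).
#' @param p_max exclusive p-value threshold (default 0.001).
#' @param signed_cc restrict to positive correlations if `TRUE`.
#' @return data.frame with columns `gene_x`, `gene_y`, `r`, `p`, `n`.
#' @export
coexpressed_pairs <- function(expr, genes = NULL, cc_min = 0.8, p_max = 0.001,
                              signed_cc = FALSE) {
  v <- expr_values(expr)
  if (is.null(genes)) genes <- rownames(v)
  missing <- setdiff(genes, rownames(v))
  if (length(missing)) {
    stop("genes absent from the expression matrix: ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  n <- ncol(v)
  if (n < 3) stop("insufficient data: need at least 3 samples")
  genes <- sort(unique(genes))
  if (length(genes) < 2) {
    return(data.frame(gene_x = character(), gene_y = character(),
                      r = numeric(), p = numeric(), n = integer()))
  }
  cm <- stats::cor(t(v[genes, , drop = FALSE]))
  idx <- which(upper.tri(cm), arr.ind = TRUE)
  r <- cm[idx]
  p <- .cor_pvalue(r, n)
  keep <- if (signed_cc) r >= cc_min else abs(r) >= cc_min
  keep <- keep & p < p_max
  out <- data.frame(gene_x = genes[idx[keep, 1]],
                    gene_y = genes[idx[keep, 2]],
                    r = r[keep], p = p[keep], n = rep.int(n, sum(keep)),
                    stringsAsFactors = FALSE)
  # upper.tri on a sorted gene set already gives gene_x < gene_y
  out[order(out$gene_x, out$gene_y), , drop = FALSE]
}

#' First-order partial correlation of a gene pair given a TF
#'
#' The mediation statistic at the heart of the network inference: the
#' correlation that remains between coexpressed genes x and y after
#' conditioning on a transcription factor z,
#' \deqn{r_{xy|z} = \frac{r_{xy} - r_{xz} r_{yz}}
#'                        {\sqrt{1 - r_{xz}^2}\sqrt{1 - r_{yz}^2}}.}
#' A small `|r_xy|z|` means z statistically explains the pair's coexpression.
#' `formula = "printed"` evaluates the published variant with numerator
#' `r_xy - r_xy * r_yz` instead (not symmetric in x and z; retained only for
#' comparison).
#'
#' Values overshooting `[-1, 1]` by at most `1e-12` (floating point) are
#' clamped; larger excursions (possible for non-PSD free-standing triples or
#' the printed variant) are returned as computed.
#'
#' @param r_xy,r_xz,r_yz pairwise Pearson correlations for genes x, y and TF z.
#' @param formula `"standard"` (default) or `"printed"`.
#' @return the partial correlation (numeric scalar).
#' @export
#' @examples
#' partial_correlation(0.9, 0, 0)          # 0.9
#' partial_correlation(0.81, 0.9, 0.9)     # 0: full mediation
partial_correlation <- function(r_xy, r_xz, r_yz,
                                formula = c("standard", "printed")) {
  formula <- match.arg(formula)
  stopifnot(is.numeric(r_xy), is.numeric(r_xz), is.numeric(r_yz))
  if (any(abs(r_xz) >= 1) || any(abs(r_yz) >= 1)) {
    stop("degenerate conditioning: |r_xz| or |r_yz| equals 1")
  }
  num <- if (formula == "standard") r_xy - r_xz * r_yz else r_xy - r_xy * r_yz
  v <- num / (sqrt(1 - r_xz^2) * sqrt(1 - r_yz^2))
  over <- abs(v) > 1 & abs(v) <= 1 + 1e-12
  v[over] <- sign(v[over])
  v
}

#' Partial correlation of a coexpressed pair conditioned on a TF, from data
#'
#' Builds the empirical correlation triple (r_xy, r_xz, r_yz) from an
#' expression matrix and returns [partial_correlation()]. Symmetric in the
#' pair: swapping `gene_x` and `gene_y` gives the identical value.
#'
#' @param expr an [expression_matrix].
#' @param gene_x,gene_y the coexpressed pair (must differ from `tf`).
#' @param tf the conditioning transcription factor gene id.
#' @inheritParams partial_correlation
#' @return the empirical first-order partial correlation.
#' @export
pcc_for_pair <- function(expr, gene_x, gene_y, tf,
                         formula = c("standard", "printed")) {
  formula <- match.arg(formula)
  if (tf %in% c(gene_x, gene_y)) {
    stop("the conditioning TF must not be a member of the pair")
  }
  v <- expr_values(expr)
  for (g in c(gene_x, gene_y, tf)) {
    if (!g %in% rownames(v)) stop("gene not in expression matrix: ", g)
  }
  x <- v[gene_x, ]; y <- v[gene_y, ]; z <- v[tf, ]
  partial_correlation(stats::cor(x, y), stats::cor(x, z), stats::cor(y, z),
                      formula = formula)
}
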
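#' Pipeline run configuration
#'
#' Bundles every threshold the network-inference and verification stages use,
#' together with the identity of the root transcription factor and a master
#' seed. Defaults are the thresholds the method is defined with: coexpression
#' requires Pearson CC >= 0.8 at p < 0.001, mediation requires a first-order
#' partial correlation |PCC| < 0.3, differential expression requires
#' FDR < 0.05 with absolute fold change >= 2, and a qPCR regulation call
#' requires fold change >= 2 at p < 0.05.
#'
#' Boundary conventions follow the printed inequalities exactly: `>=` for the
#' CC and fold-change gates (inclusive), `<` for every p-value, FDR and PCC
#' gate (exclusive).
#'
#' @param cc_min minimum absolute Pearson correlation for a coexpressed pair.
#' @param cc_p_max exclusive upper bound on the pair's correlation p-value.
#' @param pcc_max exclusive upper bound on |PCC| for a mediation call.
#' @param deg_fdr_max exclusive upper bound on BH-adjusted FDR for a DEG.
#' @param deg_min_fold minimum absolute fold change (linear scale) for a DEG.
#' @param reg_min_fold minimum qPCR fold change for a regulation call.
#' @param reg_p_max exclusive upper bound on the qPCR p-value.
#' @param root_tf gene id of the root (layer-1) transcription factor, or `NA`.
#' @param n_fragments number of equal promoter fragments for ChIP-PCR scoring.
#' @param strands `"both"` (default) or `"forward"`: strands scanned for
#'   binding elements.
#' @param pcc_formula `"standard"` for the first-order partial correlation
#'   numerator `r_xy - r_xz * r_yz`, or `"printed"` for the literal published
#'   variant `r_xy - r_xy * r_yz` (kept for comparison; see the vignette).
#' @param signed_cc if `TRUE`, the CC gate keeps only positive correlations;
#'   default applies the threshold to |r|.
#' @param reg_two_sided if `TRUE` (default) a qPCR fold change `<= 1/min_fold`
#'   also counts as regulation (down-regulation); `FALSE` gives the literal
#'   one-sided reading.
#' @param seed integer master seed or `NA`.
#'
#' @return an object of class `grn_config` (a validated list).
#' @export
#' @examples
#' cfg <- grn_config()
#' cfg$cc_min
grn_config <- function(cc_min = 0.8,
                       cc_p_max = 0.001,
                       pcc_max = 0.3,
                       deg_fdr_max = 0.05,
                       deg_min_fold = 2,
                       reg_min_fold = 2,
                       reg_p_max = 0.05,
                       root_tf = NA_character_,
                       n_fragments = 4L,
                       strands = c("both", "forward"),
                       pcc_formula = c("standard", "printed"),
                       signed_cc = FALSE,
                       reg_two_sided = TRUE,
                       seed = NA_integer_) {
  strands <- match.arg(strands)
  pcc_formula <- match.arg(pcc_formula)
  stopifnot(
    is.numeric(cc_min), cc_min > 0, cc_min <= 1,
    is.numeric(cc_p_max), cc_p_max > 0, cc_p_max <= 1,
    is.numeric(pcc_max), pcc_max > 0, pcc_max < 1,
    is.numeric(deg_fdr_max), deg_fdr_max > 0, deg_fdr_max <= 1,
    is.numeric(deg_min_fold), deg_min_fold >= 1,
    is.numeric(reg_min_fold), reg_min_fold >= 1,
    is.numeric(reg_p_max), reg_p_max > 0, reg_p_max <= 1,
    length(n_fragments) == 1L, n_fragments >= 1,
    is.logical(signed_cc), is.logical(reg_two_sided)
  )
  structure(list(
    cc_min = cc_min, cc_p_max = cc_p_max, pcc_max = pcc_max,
    deg_fdr_max = deg_fdr_max, deg_min_fold = deg_min_fold,
    reg_min_fold = reg_min_fold, reg_p_max = reg_p_max,
    root_tf = root_tf, n_fragments = as.integer(n_fragments),
    strands = strands, pcc_formula = pcc_formula,
    signed_cc = signed_cc, reg_two_sided = reg_two_sided,
    seed = seed
  ), class = "grn_config")
}

#' @export
print.grn_config <- function(x, ...) {
  cat("pcgrn run configuration\n")
  cat(sprintf("  coexpression: |CC| >= %g, p < %g%s\n", x$cc_min, x$cc_p_max,
              if (x$signed_cc) " (positive r only)" else ""))
  cat(sprintf("  mediation:    |PCC| < %g (%s formula)\n", x$pcc_max, x$pcc_formula))
  cat(sprintf("  DEG:          FDR < %g, |fold| >= %g\n", x$deg_fdr_max, x$deg_min_fold))
  cat(sprintf("  regulation:   fold >= %g (%s), p < %g\n", x$reg_min_fold,
              if (x$reg_two_sided) "two-sided" else "up only", x$reg_p_max))
  cat(sprintf("  root TF: %s | fragments: %d | strands: %s\n",
              x$root_tf, x$n_fragments, x$strands))
  invisible(x)
}
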
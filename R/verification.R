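#' Split a promoter into equal-length fragments
#'
#' Tiles the upstream region into `k` contiguous fragments (the ChIP-PCR
#' design: a 2000 bp promoter in four 500 bp tiles). Coordinates are reported
#' on the upstream axis `-region_length .. -1` (1-based inclusive, -1 being
#' the base adjacent to the transcription start). When the length is not
#' divisible by `k`, the leftmost (most upstream) fragments absorb the
#' remainder one base each.
#'
#' @param sequence promoter sequence (character or `DNAString`); its length
#'   must equal `region_length`.
#' @param k number of fragments (default 4).
#' @param region_length region length in bp (default: the sequence length).
#' @return data.frame with one row per fragment: `index` (1 = most upstream),
#'   `start`, `end` (negative upstream coordinates), `length`, `sequence`.
#'   Concatenating `sequence` over rows reproduces the input exactly.
#' @export
#' @examples
#' f <- fragment_promoter(strrep("A", 2000))
#' f[, c("index", "start", "end")]
fragment_promoter <- function(sequence, k = 4L, region_length = NULL) {
  s <- toupper(as.character(sequence))
  L <- nchar(s)
  if (is.null(region_length)) region_length <- L
  if (L != region_length) {
    stop("sequence length (", L, ") does not equal region_length (",
         region_length, ")")
  }
  if (k < 1) stop("k must be at least 1")
  if (k > L) stop("cannot split a ", L, " bp region into ", k, " fragments")
  base <- L %/% k
  lens <- rep.int(base, k) + as.integer(seq_len(k) <= L %% k)
  ends_idx <- cumsum(lens)
  starts_idx <- ends_idx - lens + 1L
  data.frame(
    index = seq_len(k),
    start = starts_idx - L - 1L,
    end = ends_idx - L - 1L,
    length = lens,
    sequence = substring(s, starts_idx, ends_idx),
    stringsAsFactors = FALSE
  )
}

#' Call significant regulation from a qPCR fold change
#'
#' A target counts as regulated when its expression fold change upon TF
#' perturbation is at least `min_fold` (inclusive, per the printed ">= 2")
#' with p below `p_max` (exclusive, per "< 0.05"). By default the call is
#' two-sided — a fold change `<= 1/min_fold` is down-regulation — because the
#' network contains both up- and down-regulated targets; `two_sided = FALSE`
#' gives the literal one-sided reading.
#'
#' @param fold qPCR fold change (> 0).
#' @param p its p-value.
#' @param min_fold,p_max thresholds (defaults 2 and 0.05).
#' @param two_sided accept fold `<= 1/min_fold` as (down-)regulation.
#' @return list with `regulated` (logical) and `direction` (`"up"` if
#'   `fold > 1`, else `"down"`).
#' @export
call_regulation <- function(fold, p, min_fold = 2, p_max = 0.05,
                            two_sided = TRUE) {
  if (!is.finite(fold) || fold <= 0) stop("fold change must be positive")
  stopifnot(min_fold >= 1, p >= 0, p <= 1)
  passes_fold <- fold >= min_fold || (two_sided && fold <= 1 / min_fold)
  list(regulated = passes_fold && p < p_max,
       direction = if (fold > 1) "up" else "down")
}

#' Classify a predicted interaction as direct, indirect or unconfirmed
#'
#' Precedence follows the validation logic: any ChIP-positive promoter
#' fragment makes the interaction a direct regulation regardless of qPCR;
#' otherwise a significant qPCR regulation call makes it indirect; otherwise
#' it is unconfirmed.
#'
#' @param chip_positive_fragments integer vector of ChIP-positive fragment
#'   indices (empty, `NULL`, or parsed from `"-"` meaning none).
#' @param qpcr_fold,qpcr_p qPCR fold change and p-value.
#' @param config a [grn_config()] supplying `reg_min_fold`, `reg_p_max`,
#'   `reg_two_sided` and `n_fragments`.
#' @return `"direct"`, `"indirect"` or `"unconfirmed"`.
#' @export
classify_interaction <- function(chip_positive_fragments, qpcr_fold, qpcr_p,
                                 config = grn_config()) {
  frags <- .parse_fragments(chip_positive_fragments)
  if (length(frags)) {
    if (any(frags < 1 | frags > config$n_fragments)) {
      stop("fragment index outside 1..", config$n_fragments)
    }
    return("direct")
  }
  reg <- call_regulation(qpcr_fold, qpcr_p, min_fold = config$reg_min_fold,
                         p_max = config$reg_p_max,
                         two_sided = config$reg_two_sided)
  if (reg$regulated) "indirect" else "unconfirmed"
}

.parse_fragments <- function(x) {
  if (is.null(x) || !length(x)) return(integer())
  if (is.character(x)) {
    x <- x[!is.na(x) & x != "-" & x != ""]
    if (!length(x)) return(integer())
    x <- unlist(strsplit(x, ","))
  }
  as.integer(x[!is.na(x)])
}

# round half away from zero (base round() is banker's rounding)
.round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Summarize verification records into confirmation percentages
#'
#' Counts direct / indirect / unconfirmed classifications for one layer pair
#' and converts them to integer percentages (nearest integer, halves away
#' from zero — the rule that turns 4/30 into 13% and 28/30 into 93%).
#' `percent_overall` counts direct plus indirect as confirmed.
#'
#' @param records data.frame with columns `regulator`, `target`,
#'   `chip_fragments`, `qpcr_fold`, `qpcr_p`, optionally `layer_pair` and a
#'   precomputed `classification`; classifications are computed via
#'   [classify_interaction()] when absent.
#' @param layer_pair optional filter, e.g. `"2-3"`.
#' @param config a [grn_config()].
#' @return list: `n`, `n_direct`, `n_indirect`, `n_unconfirmed`,
#'   `pct_direct`, `pct_indirect`, `pct_overall`.
#' @export
#' @examples
#' rec <- data.frame(chip_fragments = c(rep("1", 24), rep("-", 6)),
#'                   qpcr_fold = c(rep(1, 24), rep(3, 4), 1.2, 1.1),
#'                   qpcr_p = c(rep(1, 24), rep(0.01, 4), 0.5, 0.6))
#' summarize_verification(rec)  # 80% direct, 13% indirect, 93% overall
summarize_verification <- function(records, layer_pair = NULL,
                                   config = grn_config()) {
  stopifnot(is.data.frame(records))
  if (!is.null(layer_pair)) {
    records <- records[records$layer_pair == layer_pair, , drop = FALSE]
  }
  if (!nrow(records)) stop("no verification records", if (!is.null(layer_pair))
    paste0(" for layer pair ", layer_pair) else "")
  cls <- if ("classification" %in% names(records)) {
    records$classification
  } else {
    vapply(seq_len(nrow(records)), function(i) {
      classify_interaction(records$chip_fragments[i], records$qpcr_fold[i],
                           records$qpcr_p[i], config = config)
    }, "")
  }
  n <- length(cls)
  nd <- sum(cls == "direct"); ni <- sum(cls == "indirect")
  nu <- n - nd - ni
  list(n = n, n_direct = nd, n_indirect = ni, n_unconfirmed = nu,
       pct_direct = .round_half_away(100 * nd / n),
       pct_indirect = .round_half_away(100 * ni / n),
       pct_overall = .round_half_away(100 * (nd + ni) / n))
}

#' ChIP fold enrichment with the ChIP- baseline set to 1
#'
#' @param chip_plus_quantity abundance in the antibody (ChIP+) sample.
#' @param chip_minus_quantity abundance in the no-antibody (ChIP-) sample;
#'   must be positive (a zero baseline signals a failed control).
#' @return fold enrichment `chip_plus_quantity / chip_minus_quantity`; equal
#'   quantities give exactly 1.
#' @export
chip_fold_enrichment <- function(chip_plus_quantity, chip_minus_quantity) {
  stopifnot(chip_plus_quantity >= 0)
  if (!is.finite(chip_minus_quantity) || chip_minus_quantity <= 0) {
    stop("ChIP- baseline quantity must be positive (failed baseline)")
  }
  chip_plus_quantity / chip_minus_quantity
}

#' Relative expression by the 2^-ddCt method
#'
#' Standard relative quantification of a qPCR target against a reference gene
#' and a control condition under perfect amplification efficiency:
#' `2^-((Ct_target,treated - Ct_ref,treated) - (Ct_target,control - Ct_ref,control))`.
#'
#' @param ct_target_treated,ct_ref_treated,ct_target_control,ct_ref_control
#'   threshold cycle values (finite numerics).
#' @return fold change relative to the control condition.
#' @export
#' @examples
#' relative_expression(20, 18, 22, 19)  # ddCt = -1 -> 2
relative_expression <- function(ct_target_treated, ct_ref_treated,
                                ct_target_control, ct_ref_control) {
  cts <- c(ct_target_treated, ct_ref_treated, ct_target_control, ct_ref_control)
  if (!all(is.finite(cts))) stop("all Ct values must be finite")
  ddct <- (ct_target_treated - ct_ref_treated) -
    (ct_target_control - ct_ref_control)
  2^(-ddct)
}
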
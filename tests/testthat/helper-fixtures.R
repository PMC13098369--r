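# Shared fixtures and independent oracles. Oracles here are deliberately
# written with different machinery than the implementation (no Biostrings,
# no partial_correlation calls) so they can serve as cross-checks.

# reverse complement, pure base R
rc_chr <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", toupper(s)), "")[[1]]),
        collapse = "")
}

# sliding-window scan oracle: start offsets where every core position's base
# is in its allowed set
brute_scan_strand <- function(s, core) {
  L <- nchar(s); k <- length(core)
  if (L < k) return(integer())
  subs <- substring(s, 1:(L - k + 1L), k:L)
  ok <- rep(TRUE, length(subs))
  for (j in seq_len(k)) ok <- ok & substr(subs, j, j) %in% core[[j]]
  which(ok)
}

# full oracle matching scan_sequence()'s output contract
brute_scan <- function(s, element, strands = "both") {
  s <- toupper(s)
  k <- length(element$core)
  fwd <- brute_scan_strand(s, element$core)
  out <- if (length(fwd)) {
    data.frame(element = element$id, strand = "+", offset = fwd,
               matched = substring(s, fwd, fwd + k - 1L),
               stringsAsFactors = FALSE)
  } else NULL
  if (strands == "both") {
    rc <- rc_chr(s)
    rev <- brute_scan_strand(rc, element$core)
    if (length(rev)) {
      out <- rbind(out, data.frame(
        element = element$id, strand = "-",
        offset = nchar(s) - (rev + k - 1L) + 1L,
        matched = substring(rc, rev, rev + k - 1L),
        stringsAsFactors = FALSE))
    }
  }
  if (is.null(out)) {
    out <- data.frame(element = character(), strand = character(),
                      offset = integer(), matched = character())
  }
  out <- out[order(out$offset, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# expression_matrix from a bare value matrix, with dummy design labels
make_expr <- function(values, genotype = "WT", condition = "control") {
  n <- ncol(values)
  ids <- sprintf("%s_%s_%d", genotype, condition, seq_len(n))
  colnames(values) <- ids
  expression_matrix(values, data.frame(
    sample = ids, genotype = genotype, condition = condition,
    replicate = seq_len(n), stringsAsFactors = FALSE))
}

# a noise vector orthogonalized against the given covariates (exact-zero
# empirical correlation, for exact-mediation fixtures)
orth_noise <- function(n, ...) {
  covars <- list(...)
  e <- stats::rnorm(n)
  if (length(covars)) {
    X <- do.call(cbind, covars)
    e <- stats::residuals(stats::lm(e ~ X))
  }
  as.numeric(e)
}

# layered network at the published scale: layer sizes 1/20/39/247 and
# interlayer edge counts 20/332/4426, edges drawn as distinct pairs
make_published_scale_network <- function(seed = 1L) {
  l2 <- sprintf("T2_%02d", 1:20)
  l3 <- sprintf("T3_%02d", 1:39)
  l4 <- sprintf("S4_%03d", 1:247)
  layers <- stats::setNames(rep.int(1:4, c(1L, 20L, 39L, 247L)),
                            c("ROOT", l2, l3, l4))
  pick_pairs <- function(from, to, n_edges) {
    all_idx <- seq_len(length(from) * length(to))
    idx <- sample(all_idx, n_edges)
    data.frame(regulator = from[(idx - 1L) %% length(from) + 1L],
               target = to[(idx - 1L) %/% length(from) + 1L],
               stringsAsFactors = FALSE)
  }
  edges <- withr::with_seed(seed, rbind(
    data.frame(regulator = "ROOT", target = l2, stringsAsFactors = FALSE),
    pick_pairs(l2, l3, 332L),
    pick_pairs(l3, l4, 4426L)))
  layered_network(layers, edges)
}

# default planted benchmark: tree of 1/5/8/20 genes, 60 samples
default_benchmark <- function(noise_sd = 0.05, seed = 42L) {
  net <- generate_grn_topology(5, 8, 20, fan_in_max = 1, seed = seed)
  design <- simulation_design(noise_sd = noise_sd, seed = seed)
  list(net = net, expr = simulate_expression(net, design),
       annotation = planted_annotation(net))
}
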
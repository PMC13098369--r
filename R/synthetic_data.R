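#' Generate a planted four-layer regulatory network topology
#'
#' Builds the ground-truth object the benchmark pipeline must recover: a root
#' TF (layer 1) regulating `n2` second-layer TFs, which regulate `n3`
#' third-layer TFs, which regulate `n4` fourth-layer structural genes. Edges
#' connect consecutive layers only; the root connects to every layer-2 TF and
#' each layer-3/4 gene draws 1..`fan_in_max` parents uniformly from the layer
#' above. The default `fan_in_max = 1` yields a tree, the regime in which
#' first-order partial-correlation inference is fully identifiable (see the
#' vignette).
#'
#' @param n2,n3,n4 gene counts in layers 2, 3 and 4 (all >= 1).
#' @param fan_in_max maximum number of parents per layer-3/4 gene (>= 1).
#' @param seed integer seed; the topology is reproducible under a fixed seed.
#' @return object of class `planted_network`: fields `root_tf`, `layer2`,
#'   `layer3`, `layer4` (gene id vectors), `edges` (data.frame `regulator`,
#'   `target`), `seed`.
#' @export
#' @examples
#' net <- generate_grn_topology(5, 8, 20, seed = 42)
#' nrow(net$edges)
generate_grn_topology <- function(n2, n3, n4, fan_in_max = 1L, seed = 1L) {
  for (v in list(n2 = n2, n3 = n3, n4 = n4, fan_in_max = fan_in_max)) {
    if (length(v) != 1L || !is.finite(v) || v < 1 || v != round(v)) {
      stop("n2, n3, n4 and fan_in_max must be positive integers")
    }
  }
  root <- "L1T001"
  layer2 <- sprintf("L2T%03d", seq_len(n2))
  layer3 <- sprintf("L3T%03d", seq_len(n3))
  layer4 <- sprintf("L4S%03d", seq_len(n4))
  pick_parents <- function(children, parents) {
    do.call(rbind, lapply(children, function(ch) {
      k <- sample.int(min(fan_in_max, length(parents)), 1L)
      data.frame(regulator = sort(sample(parents, k)), target = ch,
                 stringsAsFactors = FALSE)
    }))
  }
  edges <- withr::with_seed(seed, rbind(
    data.frame(regulator = root, target = layer2, stringsAsFactors = FALSE),
    pick_parents(layer3, layer2),
    pick_parents(layer4, layer3)
  ))
  rownames(edges) <- NULL
  structure(list(root_tf = root, layer2 = layer2, layer3 = layer3,
                 layer4 = layer4, edges = edges, seed = as.integer(seed)),
            class = "planted_network")
}

#' @export
print.planted_network <- function(x, ...) {
  cat(sprintf("planted_network: 1 + %d + %d + %d genes, %d edges (seed %d)\n",
              length(x$layer2), length(x$layer3), length(x$layer4),
              nrow(x$edges), x$seed))
  invisible(x)
}

#' All gene ids of a planted network, root first
#' @param net a `planted_network`.
#' @return character vector.
#' @export
planted_genes <- function(net) {
  c(net$root_tf, net$layer2, net$layer3, net$layer4)
}

#' True layer membership of a planted network
#' @param net a `planted_network`.
#' @return named integer vector mapping gene id to layer 1..4.
#' @export
planted_layers <- function(net) {
  stats::setNames(
    rep.int(1:4, c(1L, length(net$layer2), length(net$layer3), length(net$layer4))),
    planted_genes(net)
  )
}

#' TF/structural annotation implied by a planted network
#' @param net a `planted_network`.
#' @return named character vector, values `"TF"` or `"structural"`.
#' @export
planted_annotation <- function(net) {
  stats::setNames(
    c(rep("TF", 1L + length(net$layer2) + length(net$layer3)),
      rep("structural", length(net$layer4))),
    planted_genes(net)
  )
}

#' Simulation design for the transgenic drought experiment
#'
#' Describes the expression study the simulator emulates: overexpression (OE),
#' RNAi knockdown (RE) and wild-type (WT) genotypes of the root TF, each under
#' control and drought conditions with replicated sampling. The root TF's
#' log-scale abundance is `baseline * root_effect[genotype] +
#' drought_effect * drought + noise`; downstream genes are weighted sums of
#' their parents plus independent Gaussian noise.
#'
#' @param genotypes subset of `c("OE", "RE", "WT")`.
#' @param conditions subset of `c("control", "drought")`.
#' @param replicates replicate count per genotype x condition cell (>= 2).
#' @param root_effect named multipliers on the root baseline; must satisfy
#'   OE > WT > RE > 0 when all three genotypes are present.
#' @param drought_effect additive log-scale shift under drought.
#' @param edge_weight_range interval edge weights are drawn from (uniform).
#' @param positive_weights if `TRUE` (default) all edge weights are positive;
#'   otherwise signs are random.
#' @param noise_sd per-gene Gaussian noise standard deviation (> 0).
#' @param baseline root TF log-scale baseline abundance.
#' @param seed integer seed for weights and noise.
#' @return object of class `simulation_design`.
#' @export
simulation_design <- function(genotypes = c("OE", "RE", "WT"),
                              conditions = c("control", "drought"),
                              replicates = 10L,
                              root_effect = c(OE = 4, RE = 0.3, WT = 1),
                              drought_effect = 2,
                              edge_weight_range = c(0.7, 1.0),
                              positive_weights = TRUE,
                              noise_sd = 0.05,
                              baseline = 5,
                              seed = 1L) {
  genotypes <- match.arg(genotypes, c("OE", "RE", "WT"), several.ok = TRUE)
  conditions <- match.arg(conditions, c("control", "drought"), several.ok = TRUE)
  stopifnot(replicates >= 2, noise_sd > 0,
            length(edge_weight_range) == 2,
            edge_weight_range[1] <= edge_weight_range[2],
            all(c("OE", "RE", "WT") %in% names(root_effect)))
  if (!(root_effect["OE"] > root_effect["WT"] &&
        root_effect["WT"] > root_effect["RE"] &&
        root_effect["RE"] > 0)) {
    stop("root_effect must satisfy OE > WT > RE > 0")
  }
  structure(list(genotypes = genotypes, conditions = conditions,
                 replicates = as.integer(replicates),
                 root_effect = root_effect, drought_effect = drought_effect,
                 edge_weight_range = edge_weight_range,
                 positive_weights = positive_weights,
                 noise_sd = noise_sd, baseline = baseline,
                 seed = as.integer(seed)),
            class = "simulation_design")
}

#' Simulate expression from a planted network (linear-Gaussian cascade)
#'
#' Expression is generated in topological order: the root from the design's
#' genotype/condition effects, every child gene as the weighted sum of its
#' parents plus independent Gaussian noise. With `noise_sd -> 0` every
#' regulator-target correlation approaches +/-1, which is what makes planted
#' recovery analytically transparent.
#'
#' @param net a `planted_network`.
#' @param design a [simulation_design()].
#' @return an [expression_matrix] with
#'   `length(genotypes) * length(conditions) * replicates` columns.
#' @export
simulate_expression <- function(net, design) {
  stopifnot(inherits(net, "planted_network"),
            inherits(design, "simulation_design"))
  layers <- planted_layers(net)
  # defensive acyclicity/layering check on the edge set
  lr <- layers[net$edges$regulator]; lt <- layers[net$edges$target]
  if (anyNA(lr) || anyNA(lt) || any(lt != lr + 1L)) {
    stop("structural error: edges must connect consecutive layers")
  }
  grid <- expand.grid(replicate = seq_len(design$replicates),
                      condition = design$conditions,
                      genotype = design$genotypes,
                      stringsAsFactors = FALSE)
  samples <- data.frame(
    sample = sprintf("%s_%s_%d", grid$genotype, grid$condition, grid$replicate),
    genotype = grid$genotype, condition = grid$condition,
    replicate = grid$replicate, stringsAsFactors = FALSE
  )
  genes <- planted_genes(net)
  ns <- nrow(samples)
  withr::with_seed(design$seed, {
    w <- stats::runif(nrow(net$edges), design$edge_weight_range[1],
                      design$edge_weight_range[2])
    if (!design$positive_weights) w <- w * sample(c(-1, 1), length(w), TRUE)
    vals <- matrix(0, nrow = length(genes), ncol = ns,
                   dimnames = list(genes, samples$sample))
    vals[net$root_tf, ] <-
      design$baseline * design$root_effect[samples$genotype] +
      design$drought_effect * (samples$condition == "drought") +
      stats::rnorm(ns, sd = design$noise_sd)
    for (layer in 2:4) {
      for (g in genes[layers == layer]) {
        sel <- net$edges$target == g
        contrib <- w[sel] %*% vals[net$edges$regulator[sel], , drop = FALSE]
        vals[g, ] <- contrib + stats::rnorm(ns, sd = design$noise_sd)
      }
    }
    expression_matrix(vals, samples)
  })
}

#' Generate promoter sequences with planted cis-elements
#'
#' Builds one upstream promoter per gene: i.i.d. background bases at the given
#' GC fraction, with each requested binding element inserted verbatim at a
#' random position on a random strand, without overlaps. Background is then
#' rejection-cleaned so that no registry element core occurs anywhere except
#' at the planted sites — the recorded insertion log and a motif scan agree
#' exactly, by construction.
#'
#' @param gene_ids character vector of promoter names.
#' @param length promoter length in bp (default 2000); must fit the elements.
#' @param planted named list: `gene id -> character vector of element ids`
#'   (ids from [element_registry()]); genes absent from the list get pure
#'   background.
#' @param gc background GC fraction (default 0.38, a typical plant promoter).
#' @param seed integer seed.
#' @return list with `sequences` (a named [Biostrings::DNAStringSet]) and
#'   `log`, a data.frame of ground truth: `gene`, `element`, `strand`,
#'   `insert_start`, `insert_end`, `core_start`, `core_end` (1-based, +
#'   strand coordinates; `core_start` is where [scan_sequence()] will report
#'   the hit).
#' @export
generate_promoters <- function(gene_ids, length = 2000L, planted = list(),
                               gc = 0.38, seed = 1L) {
  stopifnot(length >= 1, gc > 0, gc < 1)
  reg <- element_registry()
  reg_ids <- vapply(reg, `[[`, "", "id")
  bad <- setdiff(unlist(planted), reg_ids)
  if (length(bad)) stop("unknown element id(s): ", paste(bad, collapse = ", "))
  full_len <- vapply(reg, function(e) nchar(e$full_sequence), 0)
  if (length < max(full_len)) {
    stop("promoter length shorter than the longest element")
  }
  base_probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  withr::with_seed(seed, {
    seqs <- character(length(gene_ids))
    names(seqs) <- gene_ids
    log <- list()
    for (g in gene_ids) {
      want <- planted[[g]]
      placed <- .place_elements(g, want, reg, length)
      s <- sample(names(base_probs), length, replace = TRUE, prob = base_probs)
      if (!is.null(placed)) {
        for (i in seq_len(nrow(placed))) {
          ins <- placed$insert_seq[i]
          s[placed$insert_start[i]:placed$insert_end[i]] <-
            strsplit(ins, "")[[1]]
        }
      }
      s <- .clean_background(s, placed, reg, base_probs)
      seqs[g] <- paste(s, collapse = "")
      if (!is.null(placed)) log[[g]] <- placed
    }
    log <- if (length(log)) {
      out <- do.call(rbind, log)
      rownames(out) <- NULL
      out[, c("gene", "element", "strand", "insert_start", "insert_end",
              "core_start", "core_end")]
    } else {
      data.frame(gene = character(), element = character(), strand = character(),
                 insert_start = integer(), insert_end = integer(),
                 core_start = integer(), core_end = integer())
    }
    list(sequences = Biostrings::DNAStringSet(seqs), log = log)
  })
}

# choose non-overlapping insert positions and strands for one promoter
.place_elements <- function(gene, element_ids, reg, length) {
  if (is.null(element_ids) || !length(element_ids)) return(NULL)
  reg_by_id <- stats::setNames(reg, vapply(reg, `[[`, "", "id"))
  lens <- vapply(element_ids, function(e) nchar(reg_by_id[[e]]$full_sequence), 0L)
  if (sum(lens) > length) stop("capacity error: planted elements exceed promoter length")
  ok <- FALSE
  for (attempt in 1:200) {
    starts <- vapply(lens, function(L) sample.int(length - L + 1L, 1L), 0L)
    ends <- starts + lens - 1L
    o <- order(starts)
    if (length(starts) == 1L || all(ends[o][-length(o)] < starts[o][-1])) {
      ok <- TRUE
      break
    }
  }
  if (!ok) stop("capacity error: could not place elements without overlap")
  strand <- sample(c("+", "-"), length(element_ids), replace = TRUE)
  rows <- lapply(seq_along(element_ids), function(i) {
    el <- reg_by_id[[element_ids[i]]]
    full <- el$full_sequence
    core_off <- el$core_offset          # 1-based core start within full site
    core_len <- length(el$core)
    if (strand[i] == "+") {
      ins <- full
      cs <- starts[i] + core_off - 1L
    } else {
      ins <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(full)))
      cs <- ends[i] - (core_off + core_len - 1L) + 1L
    }
    data.frame(gene = gene, element = element_ids[i], strand = strand[i],
               insert_start = starts[i], insert_end = ends[i],
               core_start = cs, core_end = cs + core_len - 1L,
               insert_seq = ins, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# mutate background bases until no registry core occurs off the planted sites
.clean_background <- function(s, placed, reg, base_probs) {
  in_insert <- rep(FALSE, length(s))
  expected <- character()
  if (!is.null(placed)) {
    for (i in seq_len(nrow(placed))) {
      in_insert[placed$insert_start[i]:placed$insert_end[i]] <- TRUE
    }
    expected <- sprintf("%s:%s:%d", placed$element, placed$strand,
                        placed$core_start)
  }
  for (iter in 1:100) {
    seq_str <- paste(s, collapse = "")
    hits <- do.call(rbind, lapply(reg, function(el) {
      scan_sequence(seq_str, el, strands = "both")
    }))
    keys <- sprintf("%s:%s:%d", hits$element, hits$strand, hits$offset)
    spur <- hits[!keys %in% expected, , drop = FALSE]
    if (!nrow(spur)) return(s)
    for (i in seq_len(nrow(spur))) {
      span <- spur$offset[i]:(spur$offset[i] + nchar(spur$matched[i]) - 1L)
      span <- span[!in_insert[span]]
      if (!length(span)) next   # cannot happen: inserts never spawn extra cores
      pos <- span[sample.int(length(span), 1L)]
      s[pos] <- sample(setdiff(names(base_probs), s[pos]), 1L)
    }
  }
  stop("failed to clean background of spurious element matches")
}

#' Simulate a wet-lab verification table for sampled network edges
#'
#' Samples `n_sampled` edges of a planted network and assigns each an outcome:
#' direct (ChIP-positive on one of 4 promoter fragments), indirect (ChIP
#' negative but qPCR fold change >= 2 at p < 0.05), or unconfirmed (neither),
#' with the stated probabilities. Emulates the ChIP-PCR / RT-qPCR validation
#' tables the verification module scores.
#'
#' @param net a `planted_network`.
#' @param n_sampled number of edges to sample (<= total edges).
#' @param p_direct,p_indirect outcome probabilities (sum <= 1).
#' @param seed integer seed.
#' @return data.frame with columns `regulator`, `target`, `layer_pair`
#'   (`"1-2"`, `"2-3"`, `"3-4"`), `chip_fragments` (comma list or `"-"`),
#'   `qpcr_fold`, `qpcr_p`, and the generating `truth` label.
#' @export
simulate_verification_table <- function(net, n_sampled, p_direct, p_indirect,
                                        seed = 1L) {
  stopifnot(inherits(net, "planted_network"))
  if (p_direct < 0 || p_indirect < 0 || p_direct > 1 || p_indirect > 1 ||
      p_direct + p_indirect > 1) {
    stop("outcome probabilities must lie in [0,1] and sum to at most 1")
  }
  if (n_sampled > nrow(net$edges)) stop("n_sampled exceeds the number of edges")
  layers <- planted_layers(net)
  withr::with_seed(seed, {
    idx <- sample.int(nrow(net$edges), n_sampled)
    e <- net$edges[idx, , drop = FALSE]
    outcome <- sample(c("direct", "indirect", "unconfirmed"), n_sampled,
                      replace = TRUE,
                      prob = c(p_direct, p_indirect, 1 - p_direct - p_indirect))
    chip <- ifelse(outcome == "direct",
                   as.character(sample.int(4L, n_sampled, replace = TRUE)), "-")
    fold <- ifelse(outcome == "indirect", stats::runif(n_sampled, 2, 8),
                   stats::runif(n_sampled, 0.8, 1.6))
    p <- ifelse(outcome == "indirect", stats::runif(n_sampled, 0.001, 0.049),
                stats::runif(n_sampled, 0.05, 0.9))
    data.frame(regulator = e$regulator, target = e$target,
               layer_pair = sprintf("%d-%d", layers[e$regulator], layers[e$target]),
               chip_fragments = chip, qpcr_fold = fold, qpcr_p = p,
               truth = outcome, stringsAsFactors = FALSE, row.names = NULL)
  })
}
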
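# shared fixture: root z drives x and y (with mutually orthogonalized noise),
# w is an unrelated gene
make_mediation_expr <- function(n = 40, seed = 71) {
  withr::with_seed(seed, {
    z <- rnorm(n, sd = 2)
    e1 <- orth_noise(n, z)
    e2 <- orth_noise(n, z, e1)
    w <- rnorm(n)
    make_expr(rbind(root = z, A = 0.9 * z + 0.05 * e1,
                    B = 0.8 * z + 0.05 * e2, w = w))
  })
}

test_that("a mediating TF acquires edges to both members of its pair", {
  expr <- make_mediation_expr()
  pairs <- coexpressed_pairs(expr, genes = c("A", "B"))
  expect_equal(nrow(pairs), 1L)
  edges <- mediation_scan(expr, pairs, tf_candidates = "root")
  expect_setequal(paste(edges$regulator, edges$target),
                  c("root A", "root B"))
  expect_true(all(edges$min_pcc < 0.3))
  support <- attr(edges, "support")
  expect_equal(nrow(support), 1L)
  expect_equal(support$regulator, "root")
})

test_that("an unrelated TF mediates nothing", {
  expr <- make_mediation_expr()
  pairs <- coexpressed_pairs(expr, genes = c("A", "B"))
  edges <- mediation_scan(expr, pairs, tf_candidates = "w")
  expect_equal(nrow(edges), 0L)
})

test_that("the PCC gate is strictly exclusive and the CC gate inclusive", {
  expr <- make_mediation_expr()
  v <- expr_values(expr)
  # CC boundary: a threshold equal to the measured |r| keeps the pair ('>=')
  r_ab <- abs(cor(v["A", ], v["B", ]))
  expect_equal(nrow(coexpressed_pairs(expr, genes = c("A", "B"),
                                      cc_min = r_ab)), 1L)
  expect_equal(nrow(coexpressed_pairs(expr, genes = c("A", "B"),
                                      cc_min = r_ab + 1e-9)), 0L)
  # p boundary: a cutoff equal to the measured p drops the pair ('<')
  p_ab <- pearson_cc(v["A", ], v["w", ])$p_value
  expect_equal(nrow(coexpressed_pairs(expr, genes = c("A", "w"), cc_min = 0.01,
                                      p_max = p_ab)), 0L)
  expect_equal(nrow(coexpressed_pairs(expr, genes = c("A", "w"), cc_min = 0.01,
                                      p_max = p_ab * 1.01)), 1L)
  # PCC boundary: a threshold equal to the measured |pcc| emits no edge ('<')
  pairs_aw <- coexpressed_pairs(expr, genes = c("A", "w"), cc_min = 0.01,
                                p_max = 1)
  pcc <- abs(pcc_for_pair(expr, "A", "w", "B"))
  expect_equal(nrow(mediation_scan(expr, pairs_aw, "B", pcc_max = pcc)), 0L)
  expect_gt(nrow(mediation_scan(expr, pairs_aw, "B", pcc_max = pcc + 1e-9)), 0L)
})

test_that("layer assembly places a minimal chain and orphans template violations", {
  ann <- c(root = "TF", A = "TF", B = "TF", G = "structural")
  chain <- data.frame(regulator = c("root", "A", "B"),
                      target = c("A", "B", "G"))
  net <- assign_layers(chain, "root", ann)
  expect_equal(net$layers, c(root = 1L, A = 2L, B = 3L, G = 4L))
  expect_equal(net$summary$layer_sizes, c(1L, 1L, 1L, 1L))
  expect_equal(net$summary$edge_counts, c(1L, 1L, 1L))
  expect_equal(nrow(net$orphan_edges), 0L)

  # a root -> structural edge violates the template; G stays in layer 4
  with_skip <- rbind(chain, data.frame(regulator = "root", target = "G"))
  net2 <- assign_layers(with_skip, "root", ann)
  expect_equal(net2$layers[["G"]], 4L)
  expect_equal(nrow(net2$orphan_edges), 1L)
  expect_equal(net2$orphan_edges$target, "G")
  expect_equal(net2$summary$total, 3L)

  expect_error(assign_layers(chain, "G", ann), "annotated as a TF")
  expect_warning(net3 <- assign_layers(chain[0, ], "root", ann),
                 "no outgoing edges")
  expect_equal(net3$summary$total, 0L)
  expect_equal(net3$summary$edge_counts, c(0L, 0L, 0L))
})

test_that("no edge is lost: retained plus orphaned equals the scan output", {
  bench <- default_benchmark(noise_sd = 0.05, seed = 42)
  cfg <- grn_config(root_tf = bench$net$root_tf)
  net <- infer_grn(bench$expr, bench$annotation, config = cfg, prune = FALSE)
  scan <- attr(net, "scan")
  expect_equal(nrow(net$edges) + nrow(net$orphan_edges), nrow(scan))
  got <- c(paste(net$edges$regulator, net$edges$target),
           paste(net$orphan_edges$regulator, net$orphan_edges$target))
  expect_setequal(got, paste(scan$regulator, scan$target))
})

test_that("network summaries conserve edge totals under relabeling", {
  net <- make_published_scale_network(seed = 2)
  s <- summarize_network(net)
  expect_equal(s$total, nrow(net$edges))
  expect_equal(sum(s$edge_counts), s$total)
  # relabeling genes leaves the summary unchanged
  relabel <- function(x) paste0("X", x)
  net2 <- layered_network(
    stats::setNames(net$layers, relabel(names(net$layers))),
    data.frame(regulator = relabel(net$edges$regulator),
               target = relabel(net$edges$target)))
  expect_equal(summarize_network(net2)$edge_counts, s$edge_counts)

  empty <- layered_network(c(root = 1L),
                           data.frame(regulator = character(),
                                      target = character()))
  expect_equal(summarize_network(empty)$total, 0L)
})

test_that("recovery metrics handle identity, emptiness and disjoint universes", {
  truth <- generate_grn_topology(3, 4, 6, seed = 5)
  perfect <- layered_network(planted_layers(truth), truth$edges)
  m <- recover_metrics(perfect, truth)
  expect_equal(m$precision, 1)
  expect_equal(m$recall, 1)
  expect_equal(m$layer_accuracy, 1)

  empty <- layered_network(
    stats::setNames(1L, truth$root_tf),
    data.frame(regulator = character(), target = character()))
  expect_warning(m0 <- recover_metrics(empty, truth), "convention")
  expect_equal(m0$precision, 1)
  expect_equal(m0$recall, 0)

  other <- layered_network(c(zzz = 1L),
                           data.frame(regulator = character(),
                                      target = character()))
  expect_error(recover_metrics(other, truth), "share no genes")
})

test_that("the pipeline recovers the planted network across noise levels", {
  results <- lapply(c(0.5, 0.05, 0.01), function(noise) {
    bench <- default_benchmark(noise_sd = noise, seed = 42)
    cfg <- grn_config(root_tf = bench$net$root_tf)
    net <- infer_grn(bench$expr, bench$annotation, config = cfg)
    recover_metrics(net, bench$net)
  })
  # benchmark regime (noise_sd = 0.05): high-fidelity recovery
  expect_gte(results[[2]]$precision, 0.9)
  expect_gte(results[[2]]$recall, 0.9)
  # near-noiseless: exact recovery including layer membership
  expect_equal(results[[3]]$precision, 1)
  expect_equal(results[[3]]$recall, 1)
  expect_equal(results[[3]]$layer_accuracy, 1)
  # recovery does not degrade as noise shrinks
  expect_true(all(diff(vapply(results, `[[`, 0, "recall")) >= 0))
})

test_that("pruning removes the ancestor edges a global scan emits", {
  bench <- default_benchmark(noise_sd = 0.05, seed = 42)
  cfg <- grn_config(root_tf = bench$net$root_tf)
  raw <- infer_grn(bench$expr, bench$annotation, config = cfg, prune = FALSE)
  pruned <- infer_grn(bench$expr, bench$annotation, config = cfg)
  scan_edges <- attr(raw, "scan")
  # the scan emits root edges to genes in deeper layers (cross-branch
  # mediation); pruning removes them
  tl <- planted_layers(bench$net)
  deep_root <- scan_edges$regulator == bench$net$root_tf &
    tl[scan_edges$target] > 2
  expect_gt(sum(deep_root), 0)
  kept <- paste(pruned$edges$regulator, pruned$edges$target)
  expect_false(any(paste(scan_edges$regulator[deep_root],
                         scan_edges$target[deep_root]) %in% kept))
  expect_gt(recover_metrics(pruned, bench$net)$precision,
            recover_metrics(raw, bench$net)$precision)
})

test_that("identical inputs produce byte-identical network files", {
  bench <- default_benchmark(noise_sd = 0.05, seed = 42)
  cfg <- grn_config(root_tf = bench$net$root_tf)
  net1 <- infer_grn(bench$expr, bench$annotation, config = cfg)
  net2 <- infer_grn(bench$expr, bench$annotation, config = cfg)
  d <- withr::local_tempdir()
  f1 <- write_network(net1, file.path(d, "run1"))
  f2 <- write_network(net2, file.path(d, "run2"))
  for (i in seq_along(f1)) {
    expect_identical(readLines(f1[i]), readLines(f2[i]))
  }
})
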
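test_that("minimal topology parameters force the unique chain", {
  net <- generate_grn_topology(1, 1, 1, fan_in_max = 1, seed = 0)
  expect_equal(nrow(net$edges), 3L)
  expect_equal(net$edges$regulator, c(net$root_tf, net$layer2, net$layer3))
  expect_equal(net$edges$target, c(net$layer2, net$layer3, net$layer4))
})

test_that("fan_in_max = 1 forces one parent per gene at the published scale", {
  net <- generate_grn_topology(20, 39, 247, fan_in_max = 1, seed = 7)
  layer_of <- planted_layers(net)
  reg_layer <- layer_of[net$edges$regulator]
  expect_equal(unname(table(factor(reg_layer, levels = 1:3))),
               c(20L, 39L, 247L), ignore_attr = TRUE)
  expect_equal(nrow(net$edges), 306L)
})

test_that("parent counts respect fan_in_max and come from the previous layer", {
  net <- generate_grn_topology(3, 5, 10, fan_in_max = 3, seed = 1)
  layer_of <- planted_layers(net)
  for (g in c(net$layer3, net$layer4)) {
    parents <- net$edges$regulator[net$edges$target == g]
    expect_gte(length(parents), 1L)
    expect_lte(length(parents), 3L)
    expect_true(all(layer_of[parents] == layer_of[g] - 1L))
    expect_false(anyDuplicated(parents) > 0)
  }
  # root connects to every layer-2 TF
  expect_setequal(net$edges$target[net$edges$regulator == net$root_tf],
                  net$layer2)
})

test_that("topology generation is deterministic and validates its arguments", {
  a <- generate_grn_topology(4, 6, 9, fan_in_max = 2, seed = 123)
  b <- generate_grn_topology(4, 6, 9, fan_in_max = 2, seed = 123)
  expect_identical(a, b)
  c <- generate_grn_topology(4, 6, 9, fan_in_max = 2, seed = 124)
  expect_false(identical(a$edges, c$edges))
  expect_error(generate_grn_topology(0, 1, 1), "positive integers")
  expect_error(generate_grn_topology(1, 1, 1, fan_in_max = 0), "positive integers")
  expect_false(anyDuplicated(planted_genes(a)) > 0)
})

test_that("near-noiseless cascades give near-perfect parent-child correlation", {
  net <- generate_grn_topology(2, 2, 2, fan_in_max = 1, seed = 3)
  design <- simulation_design(noise_sd = 1e-9, seed = 3)
  expr <- simulate_expression(net, design)
  v <- expr_values(expr)
  for (i in seq_len(nrow(net$edges))) {
    r <- cor(v[net$edges$regulator[i], ], v[net$edges$target[i], ])
    expect_gte(abs(r), 0.999)
  }
})

test_that("the sample grid matches the design and simulation is reproducible", {
  net <- generate_grn_topology(1, 1, 1, seed = 0)
  d <- simulation_design(genotypes = "WT", conditions = "control",
                         replicates = 10, seed = 5)
  expr <- simulate_expression(net, d)
  expect_equal(ncol(expr_values(expr)), 10L)
  expect_true(all(expr$samples$genotype == "WT"))

  d2 <- simulation_design(seed = 8)
  e1 <- simulate_expression(net, d2)
  e2 <- simulate_expression(net, d2)
  expect_identical(expr_values(e1), expr_values(e2))
  expect_equal(ncol(expr_values(e1)), 60L)

  expect_error(simulation_design(replicates = 1), "replicates")
  expect_error(simulation_design(root_effect = c(OE = 1, RE = 2, WT = 1)),
               "OE > WT > RE")
  expect_error(simulation_design(noise_sd = 0), "noise_sd")
})

test_that("a promoter with no room for background is the element itself", {
  pr <- generate_promoters("g", length = 9,
                           planted = list(g = "GATA-box"), seed = 2)
  s <- as.character(pr$sequences[["g"]])
  expect_equal(nchar(s), 9L)
  if (pr$log$strand == "+") {
    expect_equal(s, "ATGATAAGG")
  } else {
    expect_equal(s, rc_chr("ATGATAAGG"))
  }
  hits <- scan_sequence(s, element_registry()[[1]], strands = "both")
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$offset, pr$log$core_start)
  expect_equal(hits$strand, pr$log$strand)
})

test_that("planted elements are recovered exactly from full-length promoters", {
  genes <- sprintf("g%02d", 1:50)
  reg <- element_registry()
  ids <- vapply(reg, `[[`, "", "id")
  planted <- lapply(seq_along(genes), function(i) {
    ids[seq_len(1 + (i %% 3))]
  })
  names(planted) <- genes
  pr <- generate_promoters(genes, length = 2000, planted = planted, seed = 11)
  for (g in genes) {
    s <- as.character(pr$sequences[[g]])
    hits <- do.call(rbind, lapply(reg, scan_sequence, seq = s, strands = "both"))
    expected <- pr$log[pr$log$gene == g, , drop = FALSE]
    expect_equal(nrow(hits), nrow(expected))
    expect_setequal(
      sprintf("%s:%s:%d", hits$element, hits$strand, hits$offset),
      sprintf("%s:%s:%d", expected$element, expected$strand,
              expected$core_start))
  }
})

test_that("promoter generation rejects unknown and oversized plantings", {
  expect_error(generate_promoters("g", planted = list(g = "TATA-box")),
               "unknown element")
  expect_error(generate_promoters("g", length = 5,
                                  planted = list(g = "GATA-box")),
               "shorter than")
  expect_error(generate_promoters("g", length = 20,
                                  planted = list(g = rep("GATA-box", 3))),
               "capacity")
})

test_that("verification outcomes follow the requested probabilities", {
  net <- generate_grn_topology(5, 8, 20, seed = 1)
  all_direct <- simulate_verification_table(net, 20, 1, 0, seed = 2)
  expect_equal(summarize_verification(all_direct)$pct_direct, 100)

  none <- simulate_verification_table(net, 5, 0, 0, seed = 3)
  s <- summarize_verification(none)
  expect_equal(s$n_unconfirmed, 5L)
  expect_equal(s$pct_overall, 0)

  # Monte-Carlo mean of the direct fraction across seeds
  fractions <- vapply(1:40, function(seed) {
    tab <- simulate_verification_table(net, 30, 0.8, 0.1333, seed = seed)
    mean(tab$truth == "direct")
  }, 0)
  se <- sqrt(0.8 * 0.2 / (30 * 40))
  expect_lt(abs(mean(fractions) - 0.8), 3 * se)

  expect_error(simulate_verification_table(net, 10, 0.9, 0.2), "probabilities")
  expect_error(simulate_verification_table(net, 1e6, 0.5, 0.2), "n_sampled")
})

test_that("sampled verification rows carry valid layer pairs and fragment indices", {
  net <- generate_grn_topology(3, 4, 6, fan_in_max = 2, seed = 9)
  tab <- simulate_verification_table(net, 10, 0.5, 0.3, seed = 4)
  expect_true(all(tab$layer_pair %in% c("1-2", "2-3", "3-4")))
  direct <- tab[tab$truth == "direct", ]
  expect_true(all(as.integer(direct$chip_fragments) %in% 1:4))
  indirect <- tab[tab$truth == "indirect", ]
  expect_true(all(indirect$qpcr_fold >= 2 & indirect$qpcr_p < 0.05))
})
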
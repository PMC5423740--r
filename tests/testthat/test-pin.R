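test_that("per-gene t tests match the closed form and t.test oracle", {
  v <- rbind(flat = c(2, 2, 2, 2, 2, 2),
             clear = c(4, 5, 6, 1, 2, 3))
  colnames(v) <- paste0("s", 1:6)
  st <- expression_study(v, rep(c("disease", "control"), each = 3))
  degs <- differential_expression(st)
  expect_equal(degs$t[degs$gene == "flat"], 0)
  expect_equal(degs$p[degs$gene == "flat"], 1)
  expect_false(degs$is_deg[degs$gene == "flat"])
  expect_equal(degs$t[degs$gene == "clear"], 3.674235, tolerance = 1e-6)
  tt <- t.test(c(4, 5, 6), c(1, 2, 3), var.equal = TRUE)
  expect_equal(degs$p[degs$gene == "clear"], tt$p.value, tolerance = 1e-10)

  big <- toy_study(n_genes = 200, n_disease = 15, n_control = 8, seed = 8)
  degs2 <- differential_expression(big)
  ora <- apply(big$values, 1, function(x) {
    t.test(x[1:15], x[16:23], var.equal = TRUE)$p.value
  })
  expect_equal(degs2$p, unname(ora), tolerance = 1e-12)
  # standardization leaves the t statistic untouched
  degs3 <- differential_expression(standardize_expression(big))
  expect_equal(degs3$t, degs2$t, tolerance = 1e-10)

  fdr <- differential_expression(big, fdr = TRUE)
  expect_equal(fdr$p_adj, p.adjust(fdr$p, "BH"))
  expect_identical(fdr$is_deg, fdr$p_adj < 0.05)
})

test_that("pairwise PCC matches cor() within each condition", {
  v <- rbind(a = c(1, 2, 3, 4, 1, 3, 5),
             b = c(1, 2, 3, 4, 1, 3, 5),
             c = -c(1, 2, 3, 4, 1, 3, 5),
             d = c(2, 7, 1, 8, 2, 8, 1))
  colnames(v) <- paste0("s", 1:7)
  st <- expression_study(v, c(rep("disease", 4), rep("control", 3)))
  ppi <- ppi_network(c("a", "a", "a"), c("b", "c", "d"), c(0.5, 0.5, 0.5))
  corr <- pairwise_pcc(st, ppi)
  i_ab <- which(corr$a == "a" & corr$b == "b")
  expect_equal(corr$pcc_disease[i_ab], 1)
  expect_equal(corr$pcc_control[i_ab], 1)
  i_ac <- which(corr$a == "a" & corr$b == "c")
  expect_equal(corr$pcc_disease[i_ac], -1)
  i_ad <- which(corr$a == "a" & corr$b == "d")
  expect_equal(corr$pcc_disease[i_ad], cor(v["a", 1:4], v["d", 1:4]),
               tolerance = 1e-12)
  expect_equal(corr$pcc_control[i_ad], cor(v["a", 5:7], v["d", 5:7]),
               tolerance = 1e-12)
  expect_equal(corr$abs_pcc_diff[i_ad],
               abs(abs(corr$pcc_disease[i_ad]) - abs(corr$pcc_control[i_ad])))

  # zero-variance endpoint within a condition -> PCC 0 with warning
  v2 <- rbind(a = c(1, 1, 1, 1, 0, 2, 4), b = c(2, 7, 1, 8, 2, 8, 1))
  colnames(v2) <- paste0("s", 1:7)
  st2 <- expression_study(v2, c(rep("disease", 4), rep("control", 3)))
  expect_warning(c2 <- pairwise_pcc(st2, ppi_network("a", "b", 0.5)),
                 "zero-variance")
  expect_equal(c2$pcc_disease, 0)
})

test_that("edge qualification implements both criteria", {
  z <- matrix(rnorm(5 * 8), 5, 8,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:8)))
  labels <- rep(c("disease", "control"), each = 4)
  pc <- pathway_collection(list(A = c("g1", "g2"), B = c("g2", "g3"),
                                C = c("g4", "g5")))
  degs <- data.frame(gene = paste0("g", 1:5), t = 0, p = 1,
                     is_deg = c(FALSE, TRUE, FALSE, FALSE, FALSE))
  corr <- data.frame(a = "g1", b = "g4", pcc_disease = 0.95,
                     pcc_control = 0.1, pcc_all = 0.5, abs_pcc_diff = 0.85)

  # shared gene g2 is a DEG
  expect_identical(qualify_edge(pc, 0L, 1L, degs, corr), "shared_deg")
  # disjoint pathways joined by a highly co-expressed PPI pair
  expect_identical(qualify_edge(pc, 0L, 2L, degs, corr), "coexpressed_ppi")
  # disjoint pathways with no crossing PPI
  expect_identical(qualify_edge(pc, 1L, 2L, degs, corr), character(0))
  expect_error(qualify_edge(pc, 1L, 1L, degs, corr), "distinct")
  expect_error(qualify_edge(pc, 0L, 7L, degs, corr), "unknown pathway")
})

test_that("edge weights sum absolute correlations once per PPI edge", {
  pc <- pathway_collection(list(A = c("g1", "g2"), B = c("g3", "g4")))
  corr <- data.frame(a = c("g1", "g2"), b = c("g3", "g4"),
                     pcc_disease = c(0.9, -0.6),
                     pcc_control = c(0.9, -0.6),
                     pcc_all = c(0.9, -0.6),
                     abs_pcc_diff = c(0, 0))
  expect_equal(edge_weight(pc, 0L, 1L, corr), 1.5)
  expect_equal(edge_weight(pc, 1L, 0L, corr), 1.5)  # symmetry
  expect_equal(edge_weight(pc, 0L, 1L, corr[0, ]), 0)

  # an edge with both endpoints in both pathways counts once
  pc2 <- pathway_collection(list(A = c("g1", "g2"), B = c("g1", "g2")))
  corr2 <- data.frame(a = "g1", b = "g2", pcc_disease = 0.5,
                      pcc_control = 0.5, pcc_all = 0.5, abs_pcc_diff = 0)
  expect_equal(edge_weight(pc2, 0L, 1L, corr2), 0.5)

  # adding a crossing PPI never decreases the weight
  w1 <- edge_weight(pc, 0L, 1L, corr[1, , drop = FALSE])
  expect_gte(edge_weight(pc, 0L, 1L, corr), w1)
})

test_that("build_pin agrees with a naive exhaustive reference", {
  for (s in 1:6) {
    inp <- toy_instance(seed = 40 + s)
    degs <- differential_expression(inp$study)
    corr <- pairwise_pcc(inp$study, inp$ppi)
    got <- build_pin(inp, degs, corr)$edges
    ref <- naive_pin(inp, degs, corr)
    expect_identical(got[c("id_a", "id_b")], ref[c("id_a", "id_b")])
    expect_equal(got$weight, ref$weight, tolerance = 1e-10)
    expect_identical(got$shared_deg, ref$shared_deg)
    expect_identical(got$coexpressed_ppi, ref$coexpressed_ppi)
    # every package edge is reproduced by the standalone operations
    if (nrow(got)) {
      for (r in seq_len(min(nrow(got), 5L))) {
        q <- qualify_edge(inp$pathways, got$id_a[r], got$id_b[r], degs, corr)
        expect_gt(length(q), 0L)
        expect_equal(edge_weight(inp$pathways, got$id_a[r], got$id_b[r],
                                 corr),
                     got$weight[r], tolerance = 1e-10)
      }
    }
  }
})

test_that("an all-null instance yields an empty network", {
  set.seed(99)
  z <- matrix(rnorm(10 * 8), 10, 8,
              dimnames = list(paste0("g", 1:10), paste0("s", 1:8)))
  st <- expression_study(z, rep(c("disease", "control"), each = 4))
  st <- standardize_expression(st)
  pc <- pathway_collection(list(A = paste0("g", 1:3), B = paste0("g", 4:6)))
  inp <- structure(list(study = st, pathways = pc,
                        ppi = ppi_network("g1", "g4", 0.9)),
                   class = "targeted_inputs")
  degs <- differential_expression(st)
  degs$is_deg <- FALSE                       # force: no DEGs
  corr <- pairwise_pcc(st, inp$ppi)
  corr$pcc_disease <- 0.1                    # force: no high co-expression
  corr$pcc_control <- 0.1
  pin <- build_pin(inp, degs, corr)
  expect_identical(nrow(pin$edges), 0L)
  expect_identical(pin$nodes, pc$ids)
})

test_that("top-fraction reduction keeps floor(fraction * edges) with tie rules", {
  pc <- pathway_collection(list(a = "g1", b = "g2", c = "g3", d = "g4"))
  edges <- data.frame(id_a = c(0L, 0L, 1L), id_b = c(1L, 2L, 2L),
                      weight = c(1, 1, 1), shared_deg = TRUE,
                      coexpressed_ppi = FALSE)
  pin <- structure(list(nodes = pc$ids, pathway_names = pc$names,
                        edges = edges),
                   class = "pathway_interaction_network")
  red <- reduce_top_fraction(pin, fraction = 2 / 3)
  expect_identical(nrow(red$edges), 2L)
  expect_identical(red$edges$id_a, c(0L, 0L))   # lexicographically smallest
  expect_identical(red$edges$id_b, c(1L, 2L))
  expect_identical(red$nodes, pin$nodes)        # isolated nodes retained

  expect_identical(reduce_top_fraction(pin, 1)$edges, pin$edges)
  expect_error(reduce_top_fraction(pin, 0), "fraction")

  # floor contract on random sizes
  set.seed(3)
  for (n in c(7L, 40L, 113L)) {
    e <- data.frame(id_a = seq_len(n) - 1L, id_b = seq_len(n),
                    weight = runif(n), shared_deg = TRUE,
                    coexpressed_ppi = FALSE)
    p <- structure(list(nodes = 0:n, pathway_names = as.character(0:n),
                        edges = e),
                   class = "pathway_interaction_network")
    for (f in c(0.05, 0.31, 0.5)) {
      expect_identical(nrow(reduce_top_fraction(p, f)$edges),
                       as.integer(floor(f * n)))
    }
  }
})

test_that("planted pathway pairs outweigh background pairs", {
  synth <- generate_study(synthetic_config(seed = 77L))
  run <- suppressMessages(suppressWarnings(
    run_pipeline(synth$study, synth$pathways, synth$ppi,
                 cv = cv_config(n_repeats = 2L))))
  pl <- synth$truth$planted_pathway_ids
  e <- run$pin$edges
  planted_w <- e$weight[e$id_a %in% pl & e$id_b %in% pl]
  background_w <- e$weight[!(e$id_a %in% pl) & !(e$id_b %in% pl) &
                             abs(e$id_a - e$id_b) > 1L]  # non-adjacent nulls
  expect_gt(length(planted_w), 0L)
  expect_gt(median(planted_w), median(background_w))
  w <- suppressWarnings(wilcox.test(planted_w, background_w,
                                    alternative = "greater"))
  expect_lt(w$p.value, 0.01)
})
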
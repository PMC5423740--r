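test_that("pathway generation respects sizes, overlap and capacity", {
  cfg <- synthetic_config(n_genes = 20L, n_pathways = 1L,
                          pathway_size_range = c(5L, 5L), n_planted = 0L)
  pc <- generate_pathways(cfg)
  expect_length(pc, 1L)
  expect_length(pc$genesets[[1L]], 5L)

  cfg0 <- synthetic_config(n_genes = 500L, n_pathways = 10L,
                           pathway_size_range = c(8L, 12L),
                           overlap_fraction = 0, n_planted = 0L)
  pc0 <- generate_pathways(cfg0)
  for (i in 1:9) {
    for (j in (i + 1):10) {
      expect_length(intersect(pc0$genesets[[i]], pc0$genesets[[j]]), 0L)
    }
  }

  tiny <- synthetic_config(n_genes = 30L, n_pathways = 10L,
                           pathway_size_range = c(8L, 12L),
                           overlap_fraction = 0, n_planted = 0L)
  expect_error(generate_pathways(tiny), "universe too small")
})

test_that("same seed gives byte-identical synthetic outputs", {
  cfg <- synthetic_config(n_pathways = 50L, overlap_fraction = 0.3,
                          seed = 1L)
  s1 <- generate_study(cfg)
  s2 <- generate_study(cfg)
  expect_identical(s1$pathways, s2$pathways)
  expect_identical(s1$ppi, s2$ppi)
  expect_identical(s1$study$values, s2$study$values)
  expect_identical(s1$truth, s2$truth)
  # and a different seed changes things
  s3 <- generate_study(synthetic_config(n_pathways = 50L,
                                        overlap_fraction = 0.3, seed = 2L))
  expect_false(identical(s1$study$values, s3$study$values))
})

test_that("PPI generation matches its edge-probability model", {
  one <- synthetic_config(n_genes = 10L, n_pathways = 1L,
                          pathway_size_range = c(5L, 5L), n_planted = 0L,
                          ppi_within_pathway_prob = 1, ppi_background_prob = 0)
  pc <- generate_pathways(one)
  expect_identical(nrow(generate_ppi(one, pc)), 10L)  # complete graph on 5

  none <- synthetic_config(n_genes = 100L, n_pathways = 3L, n_planted = 0L,
                           ppi_within_pathway_prob = 0,
                           ppi_background_prob = 0)
  expect_identical(nrow(generate_ppi(none, generate_pathways(none))), 0L)

  # background-only count within 3 SD of Binomial(C(200,2), 0.01)
  bg <- synthetic_config(n_genes = 200L, n_pathways = 2L, n_planted = 0L,
                         ppi_within_pathway_prob = 0,
                         ppi_background_prob = 0.01, seed = 42L)
  n_edges <- nrow(generate_ppi(bg, generate_pathways(bg)))
  mu <- choose(200, 2) * 0.01
  s3 <- 3 * sqrt(choose(200, 2) * 0.01 * 0.99)
  expect_gt(n_edges, mu - s3)
  expect_lt(n_edges, mu + s3)

  # every confidence inside the configured range
  rng <- synthetic_config(n_genes = 200L, n_pathways = 5L, n_planted = 0L,
                          confidence_range = c(0.3, 0.6))
  ppi <- generate_ppi(rng, generate_pathways(rng))
  expect_true(all(ppi$confidence >= 0.3 & ppi$confidence <= 0.6))
})

test_that("strong constant shifts make every affected gene a DEG", {
  miss <- 0L
  total <- 0L
  for (i in 1:50) {
    cfg <- synthetic_config(n_genes = 60L, n_pathways = 2L,
                            pathway_size_range = c(5L, 8L), n_planted = 1L,
                            effect_size = 3, affected_gene_fraction = 1,
                            severity_sd = 0, coexpression_rho = 0,
                            ppi_within_pathway_prob = 0,
                            ppi_background_prob = 0, seed = 1000L + i)
    synth <- generate_study(cfg)
    degs <- differential_expression(synth$study)
    aff <- synth$truth$affected_genes
    total <- total + 1L
    if (!all(degs$is_deg[match(aff, degs$gene)])) miss <- miss + 1L
  }
  expect_gte((total - miss) / total, 0.99)
})

test_that("module co-expression reaches the target correlation for PPI partners", {
  mean_abs <- replicate(20, {
    cfg <- synthetic_config(n_genes = 100L, n_pathways = 5L,
                            pathway_size_range = c(8L, 12L),
                            overlap_fraction = 0, n_planted = 0L,
                            coexpression_rho = 0.9,
                            ppi_within_pathway_prob = 0.4,
                            ppi_background_prob = 0,
                            seed = sample.int(10000L, 1L))
    synth <- generate_study(cfg)
    v <- synth$study$values
    r <- mapply(function(a, b) cor(v[a, ], v[b, ]),
                synth$ppi$a, synth$ppi$b)
    mean(abs(r))
  })
  expect_gte(mean(mean_abs), 0.8)
})

test_that("ground truth is consistent with the generated pathways", {
  for (s in c(3L, 17L)) {
    synth <- generate_study(synthetic_config(seed = s))
    pl <- synth$truth$planted_pathway_ids
    expect_true(all(pl %in% synth$pathways$ids))
    expect_identical(length(pl), synth$config$n_planted)
    expect_true(all(diff(sort(pl)) == 1L))  # consecutive block
    union_genes <- unique(unlist(
      lapply(pl, function(id) pathway_genes(synth$pathways, id))))
    expect_true(all(synth$truth$affected_genes %in% union_genes))
  }
})

test_that("with no effect the generator is exchangeable across groups", {
  cfg <- synthetic_config(n_genes = 1500L, n_pathways = 20L,
                          pathway_size_range = c(8L, 12L), n_planted = 0L,
                          effect_size = 0, coexpression_rho = 0,
                          ppi_within_pathway_prob = 0,
                          ppi_background_prob = 0, seed = 9L)
  synth <- generate_study(cfg)
  degs <- differential_expression(synth$study)
  # p values approximately uniform: mean near 0.5, type-I near alpha
  expect_lt(abs(mean(degs$p) - 0.5), 0.03)
  expect_lt(abs(mean(degs$is_deg) - 0.05), 0.02)
})

test_that("invalid configurations are rejected", {
  expect_error(synthetic_config(n_disease = 1L), "at least 2")
  expect_error(synthetic_config(pathway_size_range = c(3L, 8L)), ">= 5")
  expect_error(synthetic_config(n_planted = 100L, n_pathways = 10L),
               "exceeds")
  expect_error(synthetic_config(overlap_fraction = 1.2), "\\[0, 1\\]")
  expect_error(synthetic_config(confidence_range = c(0.5, 0.2)),
               "confidence_range")
})
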
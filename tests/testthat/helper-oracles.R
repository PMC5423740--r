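# Independent reference implementations and small fixture builders used
# across the suite. The oracles deliberately re-derive results with naive
# loops / textbook formulas so they share no code path with the package.

# textbook pooled two-sample t statistic
pooled_t_oracle <- function(x, y) {
  n1 <- length(x)
  n0 <- length(y)
  sp2 <- ((n1 - 1) * var(x) + (n0 - 1) * var(y)) / (n1 + n0 - 2)
  (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n0))
}

# small handmade two-group study (genes x samples), iid normal
toy_study <- function(n_genes = 20, n_disease = 6, n_control = 5,
                      seed = 1) {
  set.seed(seed)
  n <- n_disease + n_control
  v <- matrix(rnorm(n_genes * n), n_genes, n,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                              sprintf("s%02d", seq_len(n))))
  expression_study(v, c(rep("disease", n_disease), rep("control", n_control)))
}

# random small instance (study + overlapping pathways + scored PPI) built
# by hand, without the package's synthetic generator
toy_instance <- function(seed, max_pathways = 10, max_genes = 100) {
  set.seed(seed)
  n_genes <- sample(30:max_genes, 1)
  genes <- sprintf("g%03d", seq_len(n_genes))
  k <- sample(4:max_pathways, 1)
  sets <- lapply(seq_len(k), function(i) {
    sample(genes, sample(5:12, 1))
  })
  names(sets) <- sprintf("pw%02d", seq_len(k))
  pathways <- pathway_collection(sets)
  n_edges <- sample(30:80, 1)
  a <- sample(genes, n_edges, replace = TRUE)
  b <- sample(genes, n_edges, replace = TRUE)
  keep <- a != b
  ppi <- ppi_network(a[keep], b[keep], runif(sum(keep), 0.25, 1))
  n1 <- sample(6:9, 1)
  n0 <- sample(5:8, 1)
  v <- matrix(rnorm(n_genes * (n1 + n0)), n_genes, n1 + n0,
              dimnames = list(genes, sprintf("s%02d", seq_len(n1 + n0))))
  # a few shifted genes so DEGs exist
  hot <- sample(genes, ceiling(n_genes / 6))
  v[hot, seq_len(n1)] <- v[hot, seq_len(n1)] + 2
  study <- expression_study(v, c(rep("disease", n1), rep("control", n0)))
  prepare_inputs(study, pathways, ppi, min_genes = 2,
                 confidence_threshold = 0.2)
}

# naive PIN reference: scan every unordered pathway pair; criteria and
# weights re-derived with explicit loops over genes and PPI rows
naive_pin <- function(inputs, degs, corr, pcc_threshold = 0.8,
                      weight_condition = "max_abs") {
  pc <- inputs$pathways
  deg_genes <- degs$gene[degs$is_deg]
  wvals <- switch(weight_condition,
                  disease = corr$pcc_disease,
                  control = corr$pcc_control,
                  all_samples = corr$pcc_all,
                  max_abs = pmax(abs(corr$pcc_disease),
                                 abs(corr$pcc_control)))
  out <- NULL
  k <- length(pc)
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      ga <- pc$genesets[[i]]
      gb <- pc$genesets[[j]]
      shared_deg <- length(intersect(intersect(ga, gb), deg_genes)) > 0
      w <- 0
      coex <- FALSE
      if (nrow(corr)) {
        for (r in seq_len(nrow(corr))) {
          crosses <- (corr$a[r] %in% ga && corr$b[r] %in% gb) ||
            (corr$a[r] %in% gb && corr$b[r] %in% ga)
          if (crosses) {
            w <- w + abs(wvals[r])
            if (max(abs(corr$pcc_disease[r]), abs(corr$pcc_control[r])) >
                  pcc_threshold) {
              coex <- TRUE
            }
          }
        }
      }
      if (shared_deg || coex) {
        out <- rbind(out, data.frame(
          id_a = pc$ids[i], id_b = pc$ids[j], weight = w,
          shared_deg = shared_deg, coexpressed_ppi = coex))
      }
    }
  }
  if (is.null(out)) {
    out <- data.frame(id_a = integer(), id_b = integer(),
                      weight = numeric(), shared_deg = logical(),
                      coexpressed_ppi = logical())
  }
  rownames(out) <- NULL
  out
}

# tiny deterministic config for fast pipeline tests
fast_config <- function(seed = 1L, ...) {
  synthetic_config(n_genes = 400L, n_pathways = 20L, n_planted = 3L,
                   pathway_size_range = c(8L, 12L), seed = seed, ...)
}
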
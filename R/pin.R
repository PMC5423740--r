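# Pathway interaction network (PIN) construction. Two pathways are linked
# when they share at least one differentially expressed gene, or when some
# PPI pair crossing them is highly co-expressed (|PCC| > 0.8 in either
# condition). Edge weights are the sum of |PCC| over all PPI pairs crossing
# the two pathways; the network is then reduced to its top-weight fraction.

#' Per-gene differential expression by two-sample t test
#'
#' Two-sided pooled-variance t test per gene, disease vs control, with no
#' multiple-testing correction by default (raw p < alpha defines a DEG);
#' `fdr = TRUE` applies Benjamini-Hochberg and thresholds the adjusted p.
#'
#' @param study an [expression_study()] (the standardized matrix is used
#'   when present; the t statistic is invariant to per-gene affine
#'   transforms, so raw values give identical results).
#' @param alpha significance level (default 0.05).
#' @param fdr apply Benjamini-Hochberg before thresholding (default FALSE).
#' @return a `deg_table` data frame: `gene`, `t`, `p`, (`p_adj`,) `is_deg`.
#' @export
differential_expression <- function(study, alpha = 0.05, fdr = FALSE) {
  stopifnot(inherits(study, "expression_study"))
  v <- study$standardized %||% study$values
  lab <- as.character(study$labels)
  d <- lab == "disease"
  n1 <- sum(d)
  n0 <- sum(!d)
  if (n1 < 2L || n0 < 2L) stopf("both groups need at least 2 samples")
  x1 <- v[, d, drop = FALSE]
  x0 <- v[, !d, drop = FALSE]
  m1 <- rowMeans(x1)
  m0 <- rowMeans(x0)
  ss1 <- rowSums((x1 - m1)^2)
  ss0 <- rowSums((x0 - m0)^2)
  df <- n1 + n0 - 2L
  sp2 <- (ss1 + ss0) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n0))
  tt <- ifelse(se == 0, ifelse(m1 == m0, 0, Inf), (m1 - m0) / se)
  p <- 2 * stats::pt(-abs(tt), df = df)
  out <- data.frame(gene = rownames(v), t = as.numeric(tt),
                    p = as.numeric(p), stringsAsFactors = FALSE)
  if (fdr) {
    out$p_adj <- stats::p.adjust(out$p, method = "BH")
    out$is_deg <- out$p_adj < alpha
  } else {
    out$is_deg <- out$p < alpha
  }
  class(out) <- c("deg_table", "data.frame")
  attr(out, "alpha") <- alpha
  out
}

#' Pearson correlation of PPI partners within each condition
#'
#' For every PPI edge, the Pearson correlation of the two endpoint genes'
#' expression is computed within disease samples and within control samples
#' separately. A zero-variance endpoint within a condition makes the PCC
#' undefined; it is set to 0 with a warning giving the count. The
#' difference of the two conditions' absolute PCCs is exported as a
#' diagnostic column (`abs_pcc_diff`); it drives no downstream decision.
#'
#' @param study an [expression_study()].
#' @param ppi a [ppi_network()] over measured genes.
#' @return a `correlation_store` data frame: `a`, `b`, `pcc_disease`,
#'   `pcc_control`, `pcc_all`, `abs_pcc_diff`.
#' @export
pairwise_pcc <- function(study, ppi) {
  stopifnot(inherits(study, "expression_study"), inherits(ppi, "ppi_network"))
  lab <- as.character(study$labels)
  if (sum(lab == "disease") < 3L || sum(lab == "control") < 3L) {
    stopf("each condition needs at least 3 samples for correlations")
  }
  v <- study$values
  miss <- setdiff(unique(c(ppi$a, ppi$b)), rownames(v))
  if (length(miss)) {
    stopf("PPI gene(s) not measured in the study: %s",
          paste(utils::head(miss, 3L), collapse = ", "))
  }
  n_zero <- 0L
  cond_pcc <- function(cols) {
    x <- v[ppi$a, cols, drop = FALSE]
    y <- v[ppi$b, cols, drop = FALSE]
    x <- x - rowMeans(x)
    y <- y - rowMeans(y)
    nx <- sqrt(rowSums(x^2))
    ny <- sqrt(rowSums(y^2))
    r <- rowSums(x * y) / (nx * ny)
    bad <- nx == 0 | ny == 0
    n_zero <<- n_zero + sum(bad)
    r[bad] <- 0
    pmin(1, pmax(-1, as.numeric(r)))
  }
  rd <- cond_pcc(lab == "disease")
  rc <- cond_pcc(lab == "control")
  ra <- cond_pcc(rep(TRUE, length(lab)))
  if (n_zero > 0L) {
    warnf("pairwise_pcc: %d zero-variance endpoint pair(s); PCC set to 0",
          n_zero)
  }
  out <- data.frame(a = ppi$a, b = ppi$b,
                    pcc_disease = rd, pcc_control = rc, pcc_all = ra,
                    abs_pcc_diff = abs(abs(rd) - abs(rc)),
                    stringsAsFactors = FALSE)
  class(out) <- c("correlation_store", "data.frame")
  out
}

weighting_pcc <- function(corr, weight_condition) {
  switch(weight_condition,
         disease = corr$pcc_disease,
         control = corr$pcc_control,
         all_samples = corr$pcc_all,
         max_abs = pmax(abs(corr$pcc_disease), abs(corr$pcc_control)),
         stopf("unknown weight_condition '%s'", weight_condition))
}

# corr rows whose endpoints cross the (unordered) pathway pair A, B,
# i.e. a in A & b in B, or a in B & b in A; each corr row counted once.
crossing_rows <- function(corr, genes_a, genes_b) {
  (corr$a %in% genes_a & corr$b %in% genes_b) |
    (corr$a %in% genes_b & corr$b %in% genes_a)
}

#' Qualification criteria for a pathway pair
#'
#' A pathway pair qualifies as a PIN edge if it satisfies at least one of:
#' `shared_deg` - the pathways share one or more genes, at least one of
#' which is differentially expressed; `coexpressed_ppi` - some PPI pair
#' crossing the two pathways is highly co-expressed, i.e.
#' `max(|PCC_disease|, |PCC_control|) > pcc_threshold`.
#'
#' @param pathways a [pathway_collection()].
#' @param id_a,id_b distinct pathway IDs.
#' @param degs a `deg_table` from [differential_expression()].
#' @param corr a `correlation_store` from [pairwise_pcc()].
#' @param pcc_threshold co-expression threshold (default 0.8, strict).
#' @return character vector: subset of
#'   `c("shared_deg", "coexpressed_ppi")` (possibly empty).
#' @export
qualify_edge <- function(pathways, id_a, id_b, degs, corr,
                         pcc_threshold = 0.8) {
  if (id_a == id_b) stopf("qualify_edge needs two distinct pathways")
  ga <- pathway_genes(pathways, id_a)
  gb <- pathway_genes(pathways, id_b)
  out <- character()
  shared <- intersect(ga, gb)
  if (length(shared) && any(shared %in% degs$gene[degs$is_deg])) {
    out <- c(out, "shared_deg")
  }
  cr <- crossing_rows(corr, ga, gb)
  if (any(cr) &&
      any(pmax(abs(corr$pcc_disease[cr]), abs(corr$pcc_control[cr])) >
            pcc_threshold)) {
    out <- c(out, "coexpressed_ppi")
  }
  out
}

#' Weight of a pathway pair
#'
#' The sum of `|PCC|` over all PPI pairs crossing the two pathways. Each
#' unordered PPI edge contributes once, even when both endpoints lie in
#' both pathways. Which condition's PCC feeds the sum is configurable
#' (`weight_condition`; disease by default).
#'
#' @inheritParams qualify_edge
#' @param weight_condition one of `"max_abs"` (default), `"disease"`,
#'   `"control"`, `"all_samples"`.
#' @return non-negative scalar (0 when no PPI pair crosses the pathways).
#' @export
edge_weight <- function(pathways, id_a, id_b, corr,
                        weight_condition = "max_abs") {
  ga <- pathway_genes(pathways, id_a)
  gb <- pathway_genes(pathways, id_b)
  cr <- crossing_rows(corr, ga, gb)
  if (!any(cr)) return(0)
  sum(abs(weighting_pcc(corr, weight_condition)[cr]))
}

#' Build the pathway interaction network
#'
#' Evaluates the two qualification criteria for every unordered pathway
#' pair and stores qualified edges with their weights.
#'
#' @param inputs a `targeted_inputs` from [prepare_inputs()].
#' @param degs a `deg_table` from [differential_expression()].
#' @param corr a `correlation_store` from [pairwise_pcc()] on the targeted
#'   PPI network.
#' @param pcc_threshold co-expression qualification threshold (default 0.8).
#' @param weight_condition condition feeding the weight sum. The default
#'   `"max_abs"` takes, per PPI pair, the larger of the two conditions'
#'   absolute correlations (matching the qualification rule), so a pair
#'   co-expressed in either condition contributes fully; `"disease"`,
#'   `"control"` and `"all_samples"` are available. Disease-only weighting
#'   systematically down-weights dysregulated pairs whenever the disease
#'   condition adds expression variance to their genes, which is why it is
#'   not the default.
#' @return object of class `pathway_interaction_network`: `nodes` (all
#'   pathway IDs), `pathway_names`, and `edges` (data frame `id_a`, `id_b`,
#'   `weight`, `shared_deg`, `coexpressed_ppi`, canonical `id_a < id_b`).
#' @export
build_pin <- function(inputs, degs, corr, pcc_threshold = 0.8,
                      weight_condition = c("max_abs", "disease", "control",
                                           "all_samples")) {
  stopifnot(inherits(inputs, "targeted_inputs"))
  weight_condition <- match.arg(weight_condition)
  pc <- inputs$pathways
  k <- length(pc)
  key_of <- function(lo, hi) lo * k + hi  # 0-based ids, lo < hi

  # gene -> pathway-ID membership over the informative pathways
  memb <- split(
    rep(pc$ids, lengths(pc$genesets)),
    unlist(pc$genesets, use.names = FALSE)
  )

  # criterion 1: pairs sharing at least one DEG
  deg_genes <- intersect(degs$gene[degs$is_deg], names(memb))
  keys1 <- numeric(0)
  for (g in deg_genes) {
    ids <- memb[[g]]
    if (length(ids) >= 2L) {
      ids <- sort(ids)
      pr <- utils::combn(ids, 2L)
      keys1 <- c(keys1, key_of(pr[1L, ], pr[2L, ]))
    }
  }
  keys1 <- unique(keys1)

  # PPI crossing pairs: accumulate weight and the co-expression criterion
  wsum <- numeric(0)
  coex_hit <- numeric(0)
  if (nrow(corr)) {
    wabs <- abs(weighting_pcc(corr, weight_condition))
    hi_corr <- pmax(abs(corr$pcc_disease), abs(corr$pcc_control)) >
      pcc_threshold
    pa <- memb[corr$a]
    pb <- memb[corr$b]
    la <- lengths(pa)
    lb <- lengths(pb)
    n_each <- la * lb
    use <- n_each > 0L
    if (any(use)) {
      eidx <- rep.int(which(use), n_each[use])
      ia <- unlist(Map(function(p, nq) rep(p, each = nq),
                       pa[use], lb[use]), use.names = FALSE)
      ib <- unlist(Map(function(q, np) rep.int(q, np),
                       pb[use], la[use]), use.names = FALSE)
      keep <- ia != ib
      eidx <- eidx[keep]
      lo <- pmin(ia[keep], ib[keep])
      hi <- pmax(ia[keep], ib[keep])
      key <- key_of(lo, hi)
      # one contribution per (PPI edge, pathway pair)
      dup <- duplicated(paste(eidx, key))
      eidx <- eidx[!dup]
      key <- key[!dup]
      if (length(key)) {
        wsum <- rowsum(wabs[eidx], group = key)
        coex_hit <- rowsum(as.numeric(hi_corr[eidx]), group = key)
      }
    }
  }

  keys2 <- if (length(coex_hit)) {
    as.numeric(rownames(coex_hit))[coex_hit[, 1L] > 0]
  } else {
    numeric(0)
  }
  all_keys <- sort(unique(c(keys1, keys2)))
  if (length(all_keys)) {
    w <- numeric(length(all_keys))
    if (length(wsum)) {
      m <- match(all_keys, as.numeric(rownames(wsum)))
      w[!is.na(m)] <- wsum[m[!is.na(m)], 1L]
    }
    edges <- data.frame(
      id_a = as.integer(all_keys %/% k),
      id_b = as.integer(all_keys %% k),
      weight = w,
      shared_deg = all_keys %in% keys1,
      coexpressed_ppi = all_keys %in% keys2
    )
    edges <- edges[order(edges$id_a, edges$id_b), , drop = FALSE]
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(id_a = integer(), id_b = integer(),
                        weight = numeric(), shared_deg = logical(),
                        coexpressed_ppi = logical())
  }
  structure(
    list(nodes = pc$ids, pathway_names = pc$names, edges = edges),
    class = "pathway_interaction_network"
  )
}

#' @export
print.pathway_interaction_network <- function(x, ...) {
  cat(sprintf("pathway_interaction_network: %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Reduce a PIN to its top-weight fraction
#'
#' Keeps the `floor(fraction * n_edges)` highest-weight edges; ties at the
#' cut are broken by ascending `(id_a, id_b)`. Nodes are retained even when
#' they become isolated.
#'
#' @param pin a `pathway_interaction_network` from [build_pin()].
#' @param fraction fraction of edges to keep, in `(0, 1]` (default 0.05).
#' @return a reduced `pathway_interaction_network`.
#' @export
reduce_top_fraction <- function(pin, fraction = 0.05) {
  stopifnot(inherits(pin, "pathway_interaction_network"))
  if (!(fraction > 0 && fraction <= 1)) stopf("fraction must be in (0, 1]")
  e <- pin$edges
  n_keep <- floor(fraction * nrow(e))
  ord <- order(-e$weight, e$id_a, e$id_b)
  e <- e[ord[seq_len(n_keep)], , drop = FALSE]
  e <- e[order(e$id_a, e$id_b), , drop = FALSE]
  rownames(e) <- NULL
  structure(
    list(nodes = pin$nodes, pathway_names = pin$pathway_names, edges = e),
    class = "pathway_interaction_network"
  )
}

# adjacency lookup: IDs adjacent to any of `ids`
pin_neighbors <- function(pin, ids) {
  e <- pin$edges
  hit_a <- e$id_a %in% ids
  hit_b <- e$id_b %in% ids
  sort(unique(c(e$id_b[hit_a], e$id_a[hit_b])))
}
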
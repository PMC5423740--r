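# Synthetic two-group expression studies with planted dysregulated pathways,
# overlapping pathway membership and a scored PPI network whose edges
# preferentially connect co-pathway genes. The generator exists so every
# downstream stage of the pipeline is testable without external downloads;
# its defaults emulate a small case/control microarray design (15 disease vs
# 8 control samples).

#' Configuration for the synthetic study generator
#'
#' @param n_genes number of genes in the universe (named `G0001`, ... so
#'   byte-wise and numeric order coincide).
#' @param n_disease,n_control group sizes (default 15 vs 8, a small
#'   case/control design).
#' @param n_pathways number of gene sets to generate.
#' @param pathway_size_range integer `(min, max)` pathway sizes; min must be
#'   at least 5 so generated pathways survive the default size filter.
#' @param overlap_fraction fraction in `[0, 1]` of each pathway's genes
#'   shared with the previous (adjacent) pathway.
#' @param n_planted number of dysregulated (planted) pathways; chosen as a
#'   consecutive block in ID order so the planted cluster overlaps and forms
#'   a connected region of the pathway network.
#' @param planted_overlap_fraction overlap fraction used between adjacent
#'   pathways inside the planted block (default 0.45). Co-dysregulated
#'   pathways in curated collections are typically densely interlinked
#'   (nested or sibling sets sharing many genes), and their elevated
#'   overlap is what lets a crosstalk-based method see them as a cluster.
#' @param effect_size mean shift, in SD units, added to affected genes in
#'   disease samples only.
#' @param affected_gene_fraction fraction in `(0, 1]` of each planted
#'   pathway's genes that receive the shift.
#' @param severity_sd SD of the per-patient, per-pathway dysregulation
#'   severity multiplier `s_nk ~ N(1, severity_sd^2)` applied to the shift
#'   (`+effect_size * s_nk` for affected genes of planted pathway `k` in
#'   disease sample `n`), emulating heterogeneity of disease strength
#'   across patients and pathways; the expected shift remains
#'   `effect_size`. Set to 0 for a constant shift.
#' @param ppi_within_pathway_prob,ppi_background_prob probability that a
#'   within-pathway (resp. any other) gene pair is a PPI edge.
#' @param coexpression_rho target Pearson correlation between genes sharing
#'   a PPI connected component.
#' @param confidence_range `(low, high)` range of uniform PPI confidence
#'   scores, in `[0, 1]`.
#' @param seed integer RNG seed; the same seed reproduces the study exactly.
#' @return a validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_genes = 1000L,
                             n_disease = 15L,
                             n_control = 8L,
                             n_pathways = 50L,
                             pathway_size_range = c(10L, 20L),
                             overlap_fraction = 0.2,
                             n_planted = 5L,
                             planted_overlap_fraction = 0.45,
                             severity_sd = 0.8,
                             effect_size = 2,
                             affected_gene_fraction = 0.5,
                             ppi_within_pathway_prob = 0.25,
                             ppi_background_prob = 0.015,
                             coexpression_rho = 0.8,
                             confidence_range = c(0.15, 1),
                             seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes),
    n_disease = as.integer(n_disease),
    n_control = as.integer(n_control),
    n_pathways = as.integer(n_pathways),
    pathway_size_range = as.integer(pathway_size_range),
    overlap_fraction = as.numeric(overlap_fraction),
    n_planted = as.integer(n_planted),
    planted_overlap_fraction = as.numeric(planted_overlap_fraction),
    effect_size = as.numeric(effect_size),
    affected_gene_fraction = as.numeric(affected_gene_fraction),
    severity_sd = as.numeric(severity_sd),
    ppi_within_pathway_prob = as.numeric(ppi_within_pathway_prob),
    ppi_background_prob = as.numeric(ppi_background_prob),
    coexpression_rho = as.numeric(coexpression_rho),
    confidence_range = as.numeric(confidence_range),
    seed = as.integer(seed)
  )
  if (cfg$n_disease < 2L || cfg$n_control < 2L) {
    stopf("both groups need at least 2 samples")
  }
  if (cfg$n_pathways < 1L || cfg$n_genes < 1L) {
    stopf("n_pathways and n_genes must be positive")
  }
  if (length(cfg$pathway_size_range) != 2L ||
      cfg$pathway_size_range[1L] > cfg$pathway_size_range[2L]) {
    stopf("pathway_size_range must be (min, max) with min <= max")
  }
  if (cfg$pathway_size_range[1L] < 5L) {
    stopf("pathway_size_range minimum must be >= 5 so pathways survive the size filter")
  }
  probs <- c(cfg$overlap_fraction, cfg$planted_overlap_fraction,
             cfg$affected_gene_fraction,
             cfg$ppi_within_pathway_prob, cfg$ppi_background_prob,
             cfg$coexpression_rho)
  if (any(probs < 0) || any(probs > 1)) {
    stopf("fractions and probabilities must lie in [0, 1]")
  }
  if (cfg$affected_gene_fraction <= 0) {
    stopf("affected_gene_fraction must be in (0, 1]")
  }
  if (cfg$severity_sd < 0) stopf("severity_sd must be non-negative")
  if (length(cfg$confidence_range) != 2L ||
      any(cfg$confidence_range < 0) || any(cfg$confidence_range > 1) ||
      cfg$confidence_range[1L] > cfg$confidence_range[2L]) {
    stopf("confidence_range must be (low, high) within [0, 1]")
  }
  if (cfg$n_planted > cfg$n_pathways) {
    stopf("n_planted (%d) exceeds n_pathways (%d)",
          cfg$n_planted, cfg$n_pathways)
  }
  structure(cfg, class = "synthetic_config")
}

gene_universe <- function(n_genes) {
  width <- max(4L, nchar(as.character(n_genes)))
  sprintf(paste0("G%0", width, "d"), seq_len(n_genes))
}

# the planted block's position is a pure function of the config, so the
# pathway generator (which densifies the block's overlaps) and the
# expression generator (which shifts its genes) agree on it
planted_block_ids <- function(config) {
  if (config$n_planted == 0L) return(integer(0))
  with_seed(config$seed + 3L, {
    start <- sample.int(config$n_pathways - config$n_planted + 1L, 1L)
    (start - 1L):(start + config$n_planted - 2L)  # 0-based IDs
  })
}

#' Generate a pathway collection with chained overlaps
#'
#' Pathway `i` shares `ceiling(overlap_fraction * size_i)` genes with
#' pathway `i - 1`; remaining genes are drawn fresh from the universe, so
#' non-adjacent pathways are disjoint except through chained overlap.
#' Within the planted block the elevated `planted_overlap_fraction` is used
#' instead, making the dysregulated cluster densely interlinked. Names are
#' zero-padded in generation order, so IDs (alphabetical ranks) equal
#' generation order.
#'
#' @param config a [synthetic_config()].
#' @return a [pathway_collection()].
#' @export
generate_pathways <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  planted <- planted_block_ids(config)
  with_seed(config$seed, {
    genes <- gene_universe(config$n_genes)
    pool <- sample(genes)  # shuffled fresh-gene supply
    ptr <- 0L
    take_fresh <- function(k) {
      if (ptr + k > length(pool)) {
        stopf(paste0("gene universe too small: pathway demand exceeds ",
                     "%d genes"), config$n_genes)
      }
      out <- pool[(ptr + 1L):(ptr + k)]
      ptr <<- ptr + k
      out
    }
    size_choices <- seq(config$pathway_size_range[1L],
                        config$pathway_size_range[2L])
    sizes <- if (length(size_choices) == 1L) {
      rep(size_choices, config$n_pathways)
    } else {
      sample(size_choices, config$n_pathways, replace = TRUE)
    }
    sets <- vector("list", config$n_pathways)
    for (i in seq_len(config$n_pathways)) {
      if (i == 1L) {
        sets[[i]] <- take_fresh(sizes[i])
      } else {
        ov <- if ((i - 1L) %in% planted && (i - 2L) %in% planted) {
          config$planted_overlap_fraction
        } else {
          config$overlap_fraction
        }
        n_shared <- min(ceiling(ov * sizes[i]),
                        sizes[i], length(sets[[i - 1L]]))
        shared <- if (n_shared > 0L) {
          sample(sets[[i - 1L]], n_shared)
        } else {
          character()
        }
        sets[[i]] <- c(shared, take_fresh(sizes[i] - n_shared))
      }
    }
    names(sets) <- sprintf(paste0("PWY%0", max(4L, nchar(config$n_pathways)),
                                  "d"), seq_len(config$n_pathways))
    pathway_collection(sets)
  })
}

#' Generate a scored PPI network over the gene universe
#'
#' Each within-pathway gene pair becomes an edge with probability
#' `ppi_within_pathway_prob`; every other pair with
#' `ppi_background_prob`. Edge confidences are uniform in
#' `confidence_range`.
#'
#' @param config a [synthetic_config()].
#' @param pathways the [pathway_collection()] generated from the same config.
#' @return a [ppi_network()].
#' @export
generate_ppi <- function(config, pathways) {
  stopifnot(inherits(config, "synthetic_config"),
            inherits(pathways, "pathway_collection"))
  with_seed(config$seed + 1L, {
    genes <- gene_universe(config$n_genes)
    idx <- seq_along(genes)

    # unique within-pathway candidate pairs (as integer codes)
    within_keys <- numeric(0)
    for (gs in pathways$genesets) {
      gi <- sort(match(gs, genes))
      if (anyNA(gi)) stopf("pathway gene outside the configured universe")
      if (length(gi) >= 2L) {
        pr <- utils::combn(gi, 2L)
        within_keys <- c(within_keys, pr[1L, ] * (config$n_genes + 1) + pr[2L, ])
      }
    }
    within_keys <- unique(within_keys)

    sel_within <- within_keys[stats::runif(length(within_keys)) <
                                config$ppi_within_pathway_prob]

    sel_bg <- numeric(0)
    if (config$ppi_background_prob > 0 && config$n_genes >= 2L) {
      ng <- config$n_genes
      ii <- rep.int(seq_len(ng - 1L), rev(seq_len(ng - 1L)))
      jj <- unlist(lapply(seq_len(ng - 1L), function(k) (k + 1L):ng),
                   use.names = FALSE)
      keys <- ii * (ng + 1) + jj
      bg_keys <- setdiff(keys, within_keys)
      sel_bg <- bg_keys[stats::runif(length(bg_keys)) <
                          config$ppi_background_prob]
    }

    keys <- c(sel_within, sel_bg)
    if (!length(keys)) return(ppi_network())
    i <- floor(keys / (config$n_genes + 1))
    j <- keys - i * (config$n_genes + 1)
    conf <- stats::runif(length(keys), config$confidence_range[1L],
                         config$confidence_range[2L])
    ppi_network(genes[i], genes[j], conf)
  })
}

#' Generate a two-group expression study with planted pathways
#'
#' Baseline expression is i.i.d. standard normal. Co-expression follows the
#' pathway modules: each gene is attributed to the first pathway (in ID
#' order) containing it, and genes of the same module are blended with a
#' module-level latent factor (`sqrt(1 - rho) * base + sqrt(rho) * factor`),
#' so co-module genes - and hence the PPI partners the network
#' preferentially connects - have pairwise correlation ~ `coexpression_rho`
#' while marginals stay ~ N(0, 1). Genes outside every pathway stay
#' independent.
#'
#' A consecutive block of `n_planted` pathways is planted: an
#' `affected_gene_fraction` of each planted pathway's genes receives a
#' `+effect_size * s_nk` shift in disease samples only, where
#' `s_nk ~ N(1, severity_sd^2)` is a per-patient, per-pathway disease
#' severity multiplier (expected shift = `effect_size`). A gene affected
#' through several planted pathways follows the severity of the first
#' pathway (in ID order) that recruited it.
#'
#' @param config a [synthetic_config()].
#' @param pathways pathway collection from [generate_pathways()].
#' @param ppi PPI network from [generate_ppi()] (carried through so the
#'   written study and network stay paired; the co-expression structure is
#'   module-based).
#' @return a list with elements `study` (an [expression_study()]) and
#'   `truth` (list: `planted_pathway_ids`, `affected_genes`).
#' @export
generate_expression <- function(config, pathways, ppi) {
  stopifnot(inherits(config, "synthetic_config"),
            inherits(pathways, "pathway_collection"),
            inherits(ppi, "ppi_network"))
  if (config$n_planted > length(pathways)) {
    stopf("n_planted exceeds the number of generated pathways")
  }
  planted_ids <- planted_block_ids(config)
  with_seed(config$seed + 2L, {
    genes <- gene_universe(config$n_genes)
    n <- config$n_disease + config$n_control
    samples <- c(sprintf("D%02d", seq_len(config$n_disease)),
                 sprintf("N%02d", seq_len(config$n_control)))
    labels <- c(rep("disease", config$n_disease),
                rep("control", config$n_control))
    names(labels) <- samples

    x <- matrix(stats::rnorm(config$n_genes * n), nrow = config$n_genes,
                dimnames = list(genes, samples))

    rho <- config$coexpression_rho
    if (length(pathways) && rho > 0) {
      module <- rep(NA_integer_, config$n_genes)
      for (i in seq_along(pathways$genesets)) {
        gi <- match(pathways$genesets[[i]], genes)
        if (anyNA(gi)) stopf("pathway gene outside the configured universe")
        gi <- gi[is.na(module[gi])]
        module[gi] <- i
      }
      has <- which(!is.na(module))
      mods <- unique(module[has])
      fac <- matrix(stats::rnorm(length(mods) * n), nrow = length(mods))
      ci <- match(module[has], mods)
      x[has, ] <- sqrt(1 - rho) * x[has, , drop = FALSE] +
        sqrt(rho) * fac[ci, , drop = FALSE]
    }

    planted <- integer(0)
    affected <- character(0)
    if (config$n_planted > 0L) {
      planted <- planted_ids
      disease <- labels == "disease"
      for (id in planted) {
        members <- pathway_genes(pathways, id)
        k <- ceiling(config$affected_gene_fraction * length(members))
        hit <- sample(members, k)
        new_hit <- setdiff(hit, affected)
        if (config$effect_size != 0 && length(new_hit)) {
          severity <- stats::rnorm(config$n_disease, mean = 1,
                                   sd = config$severity_sd)
          x[new_hit, disease] <- x[new_hit, disease] +
            config$effect_size *
              matrix(severity, nrow = length(new_hit),
                     ncol = config$n_disease, byrow = TRUE)
        }
        affected <- c(affected, new_hit)
      }
      affected <- sort_bytes(affected)
    }

    list(
      study = expression_study(x, labels),
      truth = list(planted_pathway_ids = planted, affected_genes = affected)
    )
  })
}

#' Generate a complete synthetic study
#'
#' Convenience wrapper chaining [generate_pathways()], [generate_ppi()] and
#' [generate_expression()].
#'
#' @param config a [synthetic_config()].
#' @return list with `study`, `pathways`, `ppi`, `truth`, `config`.
#' @export
generate_study <- function(config = synthetic_config()) {
  pathways <- generate_pathways(config)
  ppi <- generate_ppi(config, pathways)
  ex <- generate_expression(config, pathways, ppi)
  list(study = ex$study, pathways = pathways, ppi = ppi,
       truth = ex$truth, config = config)
}
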
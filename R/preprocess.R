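# Filters and standardization producing the analysis-ready inputs: per-gene
# z-scores over all samples, pathways restricted to measured genes with at
# least `min_genes` of them, and the PPI network restricted to measured
# genes with confidence strictly above the threshold.

#' Collapse probe-level rows to gene symbols
#'
#' Probes mapping to the same gene are collapsed by the per-sample mean;
#' unmapped probes are dropped.
#'
#' @param raw an [expression_study()] whose rows are probe identifiers.
#' @param probe_to_gene named character vector (names = probes, values =
#'   gene symbols) or a two-column data frame (probe, gene).
#' @return an [expression_study()] with one row per gene symbol.
#' @export
collapse_probes <- function(raw, probe_to_gene) {
  stopifnot(inherits(raw, "expression_study"))
  if (is.data.frame(probe_to_gene)) {
    if (ncol(probe_to_gene) < 2L) stopf("probe map needs two columns")
    probe_to_gene <- stats::setNames(as.character(probe_to_gene[[2L]]),
                                     as.character(probe_to_gene[[1L]]))
  }
  if (!length(probe_to_gene)) stopf("empty probe-to-gene mapping")
  mapped <- intersect(rownames(raw$values), names(probe_to_gene))
  if (!length(mapped)) stopf("no probes in the study are covered by the mapping")
  sub <- raw$values[mapped, , drop = FALSE]
  grp <- as.character(probe_to_gene[mapped])
  sums <- rowsum(sub, group = grp)
  n_per <- as.vector(rowsum(rep(1, length(grp)), group = grp))
  collapsed <- sums / n_per
  expression_study(as.matrix(collapsed), raw$labels)
}

#' Standardize expression per gene across all samples
#'
#' Computes `z_mn = (g_mn - mean_m) / sd_m` where the mean and SD of gene
#' `m` are taken over all samples (both groups pooled) with the `n - 1`
#' denominator. Zero-variance genes cannot be standardized and are dropped
#' with a message giving the count.
#'
#' @param study an [expression_study()].
#' @return the study with `standardized` filled and zero-variance genes
#'   removed from both matrices.
#' @export
standardize_expression <- function(study) {
  stopifnot(inherits(study, "expression_study"))
  v <- study$values
  if (ncol(v) < 2L) stopf("standardization needs at least 2 samples")
  mu <- rowMeans(v)
  sdv <- sqrt(rowSums((v - mu)^2) / (ncol(v) - 1L))
  keep <- is.finite(sdv) & sdv > 0
  if (!any(keep)) stopf("all genes have zero variance; nothing to standardize")
  n_drop <- sum(!keep)
  if (n_drop > 0L) {
    message(sprintf("standardize_expression: dropped %d zero-variance gene(s)",
                    n_drop))
  }
  v <- v[keep, , drop = FALSE]
  z <- (v - mu[keep]) / sdv[keep]
  expression_study(v, study$labels, standardized = z)
}

#' Keep pathways with enough measured genes
#'
#' Each pathway is first restricted to genes measured in the study; pathways
#' with fewer than `min_genes` measured genes are discarded. IDs are then
#' assigned once, by alphabetical order of the surviving names, and are not
#' reassigned downstream.
#'
#' @param pathways a [pathway_collection()].
#' @param study an [expression_study()] defining the measured genes (the
#'   standardized matrix when present, else the raw one).
#' @param min_genes minimum number of measured member genes (default 5).
#' @return a filtered [pathway_collection()] (possibly empty gene-set list
#'   triggers an error from the constructor only if a set becomes empty yet
#'   passes the threshold, which cannot happen for `min_genes >= 1`).
#' @export
filter_pathways_by_size <- function(pathways, study, min_genes = 5L) {
  stopifnot(inherits(pathways, "pathway_collection"),
            inherits(study, "expression_study"))
  measured <- rownames(study$standardized %||% study$values)
  sets <- lapply(pathways$genesets, function(g) intersect(g, measured))
  keep <- lengths(sets) >= min_genes
  sets <- sets[keep]
  if (!length(sets)) {
    return(structure(
      list(names = character(), ids = integer(),
           genesets = stats::setNames(list(), character()),
           descriptions = character()),
      class = "pathway_collection"
    ))
  }
  pathway_collection(sets, descriptions = pathways$descriptions[keep])
}

#' Keep PPI edges above a confidence threshold between measured genes
#'
#' The filter is strictly greater-than: an edge at exactly the threshold is
#' removed. Both endpoints must be measured in the study.
#'
#' @param ppi a [ppi_network()].
#' @param study an [expression_study()] defining the measured genes.
#' @param threshold confidence threshold (default 0.2, unit scale).
#' @return a filtered [ppi_network()].
#' @export
filter_ppi_by_confidence <- function(ppi, study, threshold = 0.2) {
  stopifnot(inherits(ppi, "ppi_network"), inherits(study, "expression_study"))
  measured <- rownames(study$standardized %||% study$values)
  keep <- ppi$confidence > threshold & ppi$a %in% measured &
    ppi$b %in% measured
  ppi_network(ppi$a[keep], ppi$b[keep], ppi$confidence[keep])
}

#' Build the analysis-ready targeted inputs
#'
#' Standardizes the study, then applies the pathway size filter and the PPI
#' confidence filter against the standardized gene set.
#'
#' @param study an [expression_study()].
#' @param pathways a [pathway_collection()].
#' @param ppi a [ppi_network()].
#' @param min_genes minimum measured genes per pathway (default 5).
#' @param confidence_threshold PPI confidence threshold (default 0.2).
#' @return a list of class `targeted_inputs`: `study` (standardized),
#'   `pathways` (informative pathways), `ppi` (targeted PPI network).
#' @export
prepare_inputs <- function(study, pathways, ppi, min_genes = 5L,
                           confidence_threshold = 0.2) {
  study <- standardize_expression(study)
  pathways <- filter_pathways_by_size(pathways, study, min_genes = min_genes)
  ppi <- filter_ppi_by_confidence(ppi, study, threshold = confidence_threshold)
  structure(
    list(study = study, pathways = pathways, ppi = ppi),
    class = "targeted_inputs"
  )
}
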
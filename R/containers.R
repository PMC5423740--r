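#' Two-group expression study
#'
#' Container for a genes x samples expression matrix with binary sample
#' labels. Gene and sample names must be unique; labels must take the values
#' `"disease"` and `"control"` and both groups must be present.
#'
#' @param values numeric matrix, genes in rows, samples in columns, with
#'   row and column names.
#' @param labels character or factor of per-sample group labels
#'   (`"disease"`/`"control"`), one per column of `values`. May be named by
#'   sample; names are matched against `colnames(values)`.
#' @param standardized optional genes x samples matrix of per-gene
#'   standardized values (z-scores over all samples).
#' @return an object of class `expression_study` with elements `values`,
#'   `labels` (factor, levels `control`, `disease`) and `standardized`.
#' @export
expression_study <- function(values, labels, standardized = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stopf("`values` must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stopf("`values` must have gene row names and sample column names")
  }
  if (anyDuplicated(rownames(values))) {
    stopf("duplicate gene names in expression matrix")
  }
  if (anyDuplicated(colnames(values))) {
    stopf("duplicate sample names in expression matrix")
  }
  labels <- as.character(labels)
  if (!is.null(names(labels))) {
    if (!setequal(names(labels), colnames(values))) {
      stopf("label names do not match sample names")
    }
    labels <- labels[colnames(values)]
  }
  if (length(labels) != ncol(values)) {
    stopf("need one label per sample (%d labels for %d samples)",
          length(labels), ncol(values))
  }
  if (anyNA(labels)) stopf("missing label for at least one sample")
  bad <- setdiff(unique(labels), c("disease", "control"))
  if (length(bad)) {
    stopf("labels must be 'disease' or 'control' (found: %s)",
          paste(bad, collapse = ", "))
  }
  labels <- factor(labels, levels = c("control", "disease"))
  if (nlevels(droplevels(labels)) < 2L) {
    stopf("both groups (disease and control) must be present")
  }
  if (!is.null(standardized)) {
    if (!identical(dim(standardized), dim(values)) &&
        !all(rownames(standardized) %in% rownames(values))) {
      stopf("`standardized` genes must be a subset of `values` genes")
    }
  }
  structure(
    list(values = values, labels = labels, standardized = standardized),
    class = "expression_study"
  )
}

#' @export
print.expression_study <- function(x, ...) {
  cat(sprintf(
    "expression_study: %d genes x %d samples (%d disease, %d control)%s\n",
    nrow(x$values), ncol(x$values),
    sum(x$labels == "disease"), sum(x$labels == "control"),
    if (is.null(x$standardized)) "" else ", standardized"
  ))
  invisible(x)
}

#' Pathway collection with alphabetical integer IDs
#'
#' A set of named gene sets. Pathway IDs are the 0-based rank of the pathway
#' name in byte-wise alphabetical order, so IDs are a pure function of the
#' name set and do not depend on input order.
#'
#' @param genesets named list of character vectors of member genes.
#' @param descriptions optional named character vector of descriptions.
#' @return object of class `pathway_collection` with elements `names`
#'   (alphabetical), `ids` (0-based integers, aligned with `names`),
#'   `genesets` (named list in ID order) and `descriptions`.
#' @export
pathway_collection <- function(genesets, descriptions = NULL) {
  if (!is.list(genesets) || is.null(names(genesets)) ||
      any(!nzchar(names(genesets)))) {
    stopf("`genesets` must be a named list of gene vectors")
  }
  if (anyDuplicated(names(genesets))) {
    stopf("duplicate pathway names: %s",
          paste(unique(names(genesets)[duplicated(names(genesets))]),
                collapse = ", "))
  }
  if (any(lengths(genesets) == 0L)) {
    stopf("every pathway must contain at least one gene")
  }
  genesets <- lapply(genesets, function(g) unique(as.character(g)))
  ord <- order_bytes(names(genesets))
  genesets <- genesets[ord]
  nm <- names(genesets)
  desc <- rep("", length(nm))
  names(desc) <- nm
  if (!is.null(descriptions)) {
    keep <- intersect(names(descriptions), nm)
    desc[keep] <- descriptions[keep]
  }
  structure(
    list(
      names = nm,
      ids = seq_along(nm) - 1L,
      genesets = genesets,
      descriptions = desc
    ),
    class = "pathway_collection"
  )
}

#' @export
length.pathway_collection <- function(x) length(x$names)

#' @export
print.pathway_collection <- function(x, ...) {
  cat(sprintf("pathway_collection: %d pathways, %d distinct genes\n",
              length(x), length(unique(unlist(x$genesets)))))
  invisible(x)
}

#' Look up pathway member genes by ID
#'
#' @param pathways a [pathway_collection()].
#' @param id integer pathway ID (0-based alphabetical rank).
#' @return character vector of member genes.
#' @export
pathway_genes <- function(pathways, id) {
  stopifnot(inherits(pathways, "pathway_collection"))
  id <- as.integer(id)
  if (length(id) != 1L || is.na(id) || id < 0L || id >= length(pathways)) {
    stopf("unknown pathway ID: %s", paste(id, collapse = ","))
  }
  pathways$genesets[[id + 1L]]
}

#' Look up a pathway name by ID
#' @inheritParams pathway_genes
#' @return character scalar pathway name.
#' @export
pathway_name <- function(pathways, id) {
  stopifnot(inherits(pathways, "pathway_collection"))
  id <- as.integer(id)
  if (any(is.na(id) | id < 0L | id >= length(pathways))) {
    stopf("unknown pathway ID")
  }
  pathways$names[id + 1L]
}

#' Scored protein-protein interaction network
#'
#' Undirected simple graph over gene names with per-edge confidence scores in
#' `[0, 1]`. Self-loops are dropped (with a warning giving the count) and
#' duplicate unordered pairs are resolved by keeping the maximum score.
#'
#' @param a,b character vectors of interacting gene names.
#' @param confidence numeric vector of scores in `[0, 1]`.
#' @return object of class `ppi_network`: a data frame with columns `a`, `b`
#'   (canonical order: `a` precedes `b` byte-wise) and `confidence`.
#' @export
ppi_network <- function(a = character(), b = character(),
                        confidence = numeric()) {
  a <- as.character(a)
  b <- as.character(b)
  confidence <- as.numeric(confidence)
  if (length(a) != length(b) || length(a) != length(confidence)) {
    stopf("`a`, `b` and `confidence` must have equal length")
  }
  if (anyNA(confidence) || any(confidence < 0) || any(confidence > 1)) {
    stopf("confidence scores must lie in [0, 1]")
  }
  if (length(a)) {
    cp <- pair_canonical(a, b)
    n_self <- sum(cp$degenerate)
    if (n_self > 0L) {
      warnf("dropped %d self-loop(s) from PPI network", n_self)
    }
    keep <- !cp$degenerate
    a <- cp$a[keep]
    b <- cp$b[keep]
    confidence <- confidence[keep]
    if (length(a)) {
      key <- paste(a, b, sep = "\r")
      if (anyDuplicated(key)) {
        best <- tapply(confidence, key, max)
        first <- !duplicated(key)
        a <- a[first]
        b <- b[first]
        confidence <- as.numeric(best[paste(a, b, sep = "\r")])
      }
      o <- order_bytes(a, b)
      a <- a[o]
      b <- b[o]
      confidence <- confidence[o]
    }
  }
  structure(
    data.frame(a = a, b = b, confidence = confidence,
               stringsAsFactors = FALSE),
    class = c("ppi_network", "data.frame")
  )
}

#' @export
print.ppi_network <- function(x, ...) {
  cat(sprintf("ppi_network: %d edges over %d genes\n",
              nrow(x), length(unique(c(x$a, x$b)))))
  invisible(x)
}
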
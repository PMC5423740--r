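# PCA-based pathway activity: each pathway's per-sample activity is the
# first principal component of the samples x member-genes standardized
# submatrix. The seed pathway is the one whose activity changes most
# between groups (largest absolute two-sample t statistic).

#' Compute the pathway activity matrix
#'
#' For each pathway the standardized member-gene submatrix (samples as
#' observations, genes as variables, column-centered) is decomposed by SVD;
#' the PC1 sample coordinates are the activity scores and the unit-norm gene
#' loading vector is stored. The PC sign is arbitrary, so it is fixed
#' deterministically: the loading coefficient with the largest absolute
#' value is made positive, ties resolved toward the alphabetically first
#' gene (genes are processed in byte-wise alphabetical order, which also
#' makes the result invariant to gene order in the input sets).
#'
#' @param inputs a `targeted_inputs` object from [prepare_inputs()].
#' @param min_genes minimum usable genes a pathway must have (default 2);
#'   a pathway below this triggers an error naming it. With `min_genes = 1`
#'   a single-gene pathway's activity is the gene's centered z-score itself.
#' @return object of class `activity_matrix`: `scores` (pathways x samples),
#'   `pathway_ids`, `samples`, `loadings` (named list of unit-norm gene
#'   weight vectors).
#' @export
compute_activity_matrix <- function(inputs, min_genes = 2L) {
  stopifnot(inherits(inputs, "targeted_inputs"))
  z <- inputs$study$standardized
  if (is.null(z)) stopf("inputs study must be standardized")
  pc <- inputs$pathways
  k <- length(pc)
  if (k == 0L) stopf("no pathways to score")
  n <- ncol(z)
  scores <- matrix(NA_real_, nrow = k, ncol = n,
                   dimnames = list(pc$names, colnames(z)))
  loadings <- vector("list", k)
  names(loadings) <- pc$names
  for (i in seq_len(k)) {
    genes <- sort_bytes(intersect(pc$genesets[[i]], rownames(z)))
    if (length(genes) < min_genes) {
      stopf("pathway '%s' has %d usable gene(s); needs >= %d",
            pc$names[i], length(genes), min_genes)
    }
    x <- t(z[genes, , drop = FALSE])            # samples x genes
    x <- scale(x, center = TRUE, scale = FALSE)
    sv <- svd(x, nu = 1L, nv = 1L)
    v1 <- sv$v[, 1L]
    s1 <- sv$u[, 1L] * sv$d[1L]
    j <- which.max(abs(v1))                     # first max = alphabetical tie-break
    if (v1[j] < 0) {
      v1 <- -v1
      s1 <- -s1
    }
    names(v1) <- genes
    scores[i, ] <- s1
    loadings[[i]] <- v1
  }
  structure(
    list(scores = scores, pathway_ids = pc$ids, samples = colnames(z),
         loadings = loadings),
    class = "activity_matrix"
  )
}

#' @export
print.activity_matrix <- function(x, ...) {
  cat(sprintf("activity_matrix: %d pathways x %d samples\n",
              nrow(x$scores), ncol(x$scores)))
  invisible(x)
}

#' Absolute two-sample t statistic of a pathway's activity
#'
#' Measures the change in activity between disease and control samples as
#' the absolute value of the two-sample t statistic (pooled variance by
#' default, Welch available).
#'
#' @param scores numeric vector of per-sample activity.
#' @param labels factor/character of group labels (`disease`/`control`).
#' @param type `"pooled_t"` (default) or `"welch_t"`.
#' @return non-negative scalar. Equal means yield 0; unequal means with
#'   zero pooled variance yield `Inf`.
#' @export
activity_change_statistic <- function(scores, labels,
                                      type = c("pooled_t", "welch_t")) {
  type <- match.arg(type)
  labels <- as.character(labels)
  d <- scores[labels == "disease"]
  c0 <- scores[labels == "control"]
  if (length(d) < 2L || length(c0) < 2L) {
    stopf("both groups need at least 2 samples")
  }
  md <- mean(d)
  mc <- mean(c0)
  vd <- stats::var(d)
  vc <- stats::var(c0)
  if (type == "pooled_t") {
    sp2 <- ((length(d) - 1L) * vd + (length(c0) - 1L) * vc) /
      (length(d) + length(c0) - 2L)
    se <- sqrt(sp2 * (1 / length(d) + 1 / length(c0)))
  } else {
    se <- sqrt(vd / length(d) + vc / length(c0))
  }
  if (se == 0) {
    return(if (md == mc) 0 else Inf)
  }
  abs((md - mc) / se)
}

#' Select the seed pathway
#'
#' The seed is the pathway with the maximum activity change statistic; ties
#' are broken toward the smallest pathway ID.
#'
#' @param activity an `activity_matrix` from [compute_activity_matrix()].
#' @param labels per-sample group labels, aligned with `activity$samples`.
#' @param type statistic flavour, see [activity_change_statistic()].
#' @return object of class `seed_result`: `seed_id`, `statistic`, and
#'   `per_pathway_statistics` (data frame: id, name, statistic).
#' @export
select_seed <- function(activity, labels, type = c("pooled_t", "welch_t")) {
  stopifnot(inherits(activity, "activity_matrix"))
  type <- match.arg(type)
  if (nrow(activity$scores) == 0L) stopf("empty activity matrix")
  stat <- apply(activity$scores, 1L, activity_change_statistic,
                labels = labels, type = type)
  tab <- data.frame(
    id = activity$pathway_ids,
    name = rownames(activity$scores),
    statistic = as.numeric(stat),
    stringsAsFactors = FALSE
  )
  best <- order(-tab$statistic, tab$id)[1L]
  structure(
    list(seed_id = tab$id[best], statistic = tab$statistic[best],
         per_pathway_statistics = tab),
    class = "seed_result"
  )
}

#' @export
print.seed_result <- function(x, ...) {
  nm <- x$per_pathway_statistics$name[
    x$per_pathway_statistics$id == x$seed_id]
  cat(sprintf("seed pathway: %s (ID %d), |t| = %.4f\n",
              nm, x$seed_id, x$statistic))
  invisible(x)
}
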
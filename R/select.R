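# Greedy forward selection of a dysregulated pathway set: starting from the
# seed pathway, neighbours in the reduced PIN are added one at a time
# whenever they improve the repeated cross-validated SVM AUC, using common
# fold splits across candidates so comparisons are paired.

#' Cross-validation configuration
#'
#' @param n_folds folds per repeat (default 5).
#' @param n_repeats repeats of the k-fold split (default 100; the mean AUC
#'   over repeats is the reported performance).
#' @param base_seed integer; repeat `r` draws its fold assignment from seed
#'   `base_seed + r`, so identical configs give identical splits.
#' @param stratified preserve class proportions per fold (default TRUE).
#' @param svm_cost linear-SVM cost parameter C (default 1).
#' @param min_improvement minimum mean-AUC gain required to accept a
#'   candidate during greedy growth (default 1e-6, i.e. strict improvement).
#' @return list of class `cv_config`.
#' @export
cv_config <- function(n_folds = 5L, n_repeats = 100L, base_seed = 1L,
                      stratified = TRUE, svm_cost = 1,
                      min_improvement = 1e-6) {
  if (n_folds < 2L) stopf("n_folds must be >= 2")
  if (n_repeats < 1L) stopf("n_repeats must be >= 1")
  if (svm_cost <= 0) stopf("svm_cost must be positive")
  structure(
    list(n_folds = as.integer(n_folds), n_repeats = as.integer(n_repeats),
         base_seed = as.integer(base_seed), stratified = isTRUE(stratified),
         svm_cost = as.numeric(svm_cost),
         min_improvement = as.numeric(min_improvement)),
    class = "cv_config"
  )
}

# fold assignment (1..k) per sample; stratified: shuffle within class and
# deal round-robin so class counts per fold differ by at most one
make_folds <- function(labels, n_folds, seed, stratified = TRUE) {
  labels <- as.character(labels)
  n <- length(labels)
  with_seed(seed, {
    fold <- integer(n)
    if (stratified) {
      for (cl in unique(labels)) {
        idx <- sample(which(labels == cl))
        fold[idx] <- rep_len(seq_len(n_folds), length(idx))
      }
    } else {
      fold <- sample(rep_len(seq_len(n_folds), n))
    }
    fold
  })
}

#' Area under the ROC curve from decision values
#'
#' Rank (Mann-Whitney) AUC of `scores` for separating disease (positive)
#' from control, with ties handled by midranks.
#'
#' @param scores numeric decision values, higher = more disease-like.
#' @param labels group labels aligned with `scores`.
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(scores, labels) {
  labels <- as.character(labels)
  pos <- labels == "disease"
  n1 <- sum(pos)
  n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) stopf("AUC needs both classes")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# linear SVM decision values for the test rows, oriented so that higher
# means more disease-like; features standardized by training-fold moments
svm_decision <- function(x_train, y_train, x_test, cost) {
  mu <- colMeans(x_train)
  sdv <- apply(x_train, 2L, stats::sd)
  sdv[!is.finite(sdv) | sdv == 0] <- 1
  xt <- sweep(sweep(x_train, 2L, mu), 2L, sdv, "/")
  xs <- sweep(sweep(x_test, 2L, mu), 2L, sdv, "/")
  fit <- e1071::svm(xt, y_train, kernel = "linear", cost = cost,
                    scale = FALSE, type = "C-classification")
  pr <- stats::predict(fit, xs, decision.values = TRUE)
  dv <- as.numeric(attr(pr, "decision.values")[, 1L])
  # libsvm orients decision values toward the first-seen training class
  first <- fit$levels[fit$labels[1L]]
  if (identical(first, "control")) dv <- -dv
  dv
}

#' Mean repeated cross-validated SVM AUC of a feature set
#'
#' For each repeat, samples are split into stratified folds; a linear SVM is
#' trained on the training folds and decision values are computed for the
#' held-out fold. The out-of-fold decision values of the whole repeat are
#' pooled into a single AUC (robust when small folds carry few controls),
#' and the mean over repeats is returned. Fold splits depend only on the
#' labels and `cv`, never on the features, so candidate feature sets
#' evaluated under the same config share identical splits.
#'
#' @param features samples x features numeric matrix (or vector).
#' @param labels per-sample group labels.
#' @param cv a [cv_config()].
#' @return mean AUC over repeats.
#' @export
cv_auc <- function(features, labels, cv = cv_config()) {
  if (is.vector(features)) features <- matrix(features, ncol = 1L)
  labels <- as.character(labels)
  if (length(unique(labels)) < 2L) stopf("labels contain a single class")
  if (nrow(features) != length(labels)) {
    stopf("features rows (%d) must match labels (%d)",
          nrow(features), length(labels))
  }
  y <- factor(labels, levels = c("control", "disease"))
  aucs <- numeric(cv$n_repeats)
  for (r in seq_len(cv$n_repeats)) {
    fold <- make_folds(labels, cv$n_folds, seed = cv$base_seed + r,
                       stratified = cv$stratified)
    dv <- numeric(length(labels))
    for (f in seq_len(cv$n_folds)) {
      test <- fold == f
      if (!any(test)) next
      dv[test] <- svm_decision(features[!test, , drop = FALSE], y[!test],
                               features[test, , drop = FALSE], cv$svm_cost)
    }
    aucs[r] <- auc_score(dv, labels)
  }
  mean(aucs)
}

#' Selection result constructor
#'
#' @param seed_id seed pathway ID.
#' @param seed_statistic the seed's activity change statistic.
#' @param selected_ids ordered selected pathway IDs (seed first).
#' @param auc_trace mean AUC after each addition (same length as
#'   `selected_ids`).
#' @return list of class `selection_result`.
#' @export
selection_result <- function(seed_id, seed_statistic, selected_ids,
                             auc_trace) {
  if (length(selected_ids) != length(auc_trace)) {
    stopf("auc_trace must have one entry per selected pathway")
  }
  if (anyDuplicated(selected_ids)) stopf("selected_ids must be distinct")
  structure(
    list(seed_id = as.integer(seed_id),
         seed_statistic = as.numeric(seed_statistic),
         selected_ids = as.integer(selected_ids),
         auc_trace = as.numeric(auc_trace),
         final_auc = as.numeric(auc_trace[length(auc_trace)]),
         n_pathways = length(selected_ids)),
    class = "selection_result"
  )
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf(
    "selection_result: %d pathway(s), seed ID %d (|t| = %.4f), final AUC %.4f\n",
    x$n_pathways, x$seed_id, x$seed_statistic, x$final_auc))
  invisible(x)
}

#' Greedily grow a pathway set from the seed to maximise CV AUC
#'
#' Starting from the seed pathway, candidates are the pathways adjacent (in
#' the reduced PIN) to any already-selected pathway. At each step every
#' candidate is scored by [cv_auc()] on the activity features of the current
#' set plus the candidate, under identical fold splits; the best candidate
#' is added if it improves the mean AUC by more than
#' `cv$min_improvement` (ties broken toward the smallest pathway ID).
#' Growth stops when no candidate improves or candidates are exhausted, so
#' the AUC trace is strictly increasing.
#'
#' @param seed a `seed_result` from [select_seed()] (or a bare pathway ID,
#'   in which case `seed_statistic` is recorded as `NA`).
#' @param pin_reduced the reduced `pathway_interaction_network`.
#' @param activity an `activity_matrix` over the same pathways.
#' @param labels per-sample group labels aligned with `activity$samples`.
#' @param cv a [cv_config()].
#' @return a [selection_result()].
#' @export
greedy_select <- function(seed, pin_reduced, activity, labels,
                          cv = cv_config()) {
  stopifnot(inherits(pin_reduced, "pathway_interaction_network"),
            inherits(activity, "activity_matrix"))
  if (inherits(seed, "seed_result")) {
    seed_id <- seed$seed_id
    seed_stat <- seed$statistic
  } else {
    seed_id <- as.integer(seed)
    seed_stat <- NA_real_
  }
  if (!seed_id %in% activity$pathway_ids) {
    stopf("seed pathway ID %d is absent from the activity matrix", seed_id)
  }
  feat <- function(ids) {
    t(activity$scores[match(ids, activity$pathway_ids), , drop = FALSE])
  }
  if (!seed_id %in% c(pin_reduced$edges$id_a, pin_reduced$edges$id_b)) {
    warnf("seed pathway %d has no edges in the reduced PIN; returning singleton",
          seed_id)
  }
  current <- seed_id
  trace <- cv_auc(feat(current), labels, cv)
  repeat {
    cand <- setdiff(pin_neighbors(pin_reduced, current), current)
    cand <- intersect(cand, activity$pathway_ids)
    if (!length(cand)) break
    cand <- sort(cand)
    scores <- vapply(cand, function(cid) {
      cv_auc(feat(c(current, cid)), labels, cv)
    }, numeric(1L))
    best <- order(-scores, cand)[1L]
    if (scores[best] - trace[length(trace)] > cv$min_improvement) {
      current <- c(current, cand[best])
      trace <- c(trace, scores[best])
    } else {
      break
    }
  }
  selection_result(seed_id, seed_stat, current, trace)
}
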
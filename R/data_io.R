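# Readers and writers for the standard formats the pipeline touches:
# expression TSV (+ label sidecar), Broad-dialect GMT, 3-column PPI TSV,
# pathway-network edge lists and result JSON. All readers reject malformed
# input rather than silently coercing it.

#' Read a genes x samples expression matrix from TSV
#'
#' The file must have a header of sample names, a first column of gene names
#' and numeric values elsewhere. Labels are supplied either as a designated
#' row of the matrix (`label_row_name`) or as a sidecar two-column TSV /
#' named vector (`labels`).
#'
#' @param path path to the tab-separated expression file.
#' @param labels either a path to a two-column TSV (sample, label; no
#'   header) or a character vector of labels named by sample. Ignored when
#'   `label_row_name` is given.
#' @param label_row_name optional name of the row inside the matrix that
#'   carries the group labels.
#' @return an [expression_study()].
#' @export
read_expression_tsv <- function(path, labels = NULL, label_row_name = NULL) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = "character",
                          fill = FALSE, blank.lines.skip = FALSE)
  if (ncol(df) < 2L) stopf("expression file needs a gene column and >=1 sample")
  genes <- df[[1L]]
  samples <- colnames(df)[-1L]
  body <- df[, -1L, drop = FALSE]

  lab <- NULL
  if (!is.null(label_row_name)) {
    hit <- which(genes == label_row_name)
    if (length(hit) != 1L) {
      stopf("label row '%s' not found exactly once", label_row_name)
    }
    lab <- as.character(unlist(body[hit, ], use.names = FALSE))
    names(lab) <- samples
    genes <- genes[-hit]
    body <- body[-hit, , drop = FALSE]
  } else if (is.character(labels) && length(labels) == 1L &&
             file.exists(labels)) {
    ldf <- utils::read.delim(labels, header = FALSE, sep = "\t",
                             colClasses = "character", fill = FALSE)
    if (ncol(ldf) != 2L) stopf("label sidecar must have two columns")
    lab <- ldf[[2L]]
    names(lab) <- ldf[[1L]]
  } else if (!is.null(labels)) {
    lab <- labels
  } else {
    stopf("sample labels are required (via `labels` or `label_row_name`)")
  }
  if (!all(samples %in% names(lab))) {
    stopf("missing label for sample(s): %s",
          paste(setdiff(samples, names(lab)), collapse = ", "))
  }
  if (anyDuplicated(genes)) {
    stopf("duplicate gene row(s): %s (collapse probes via collapse_probes())",
          paste(unique(genes[duplicated(genes)]), collapse = ", "))
  }
  suppressWarnings(vals <- vapply(body, as.numeric, numeric(nrow(body))))
  vals <- matrix(vals, nrow = length(genes),
                 dimnames = list(genes, samples))
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)
    stopf("non-numeric expression value at gene '%s', sample '%s'",
          genes[bad[1L, 1L]], samples[bad[1L, 2L]])
  }
  expression_study(vals, lab[samples])
}

#' Write an expression study to TSV (matrix + label sidecar)
#'
#' @param study an [expression_study()].
#' @param path output path for the matrix TSV.
#' @param labels_path optional output path for the two-column label sidecar.
#' @return invisibly, `path`.
#' @export
write_expression_tsv <- function(study, path, labels_path = NULL) {
  stopifnot(inherits(study, "expression_study"))
  df <- data.frame(gene = rownames(study$values),
                   study$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(labels_path)) {
    utils::write.table(
      data.frame(sample = colnames(study$values),
                 label = as.character(study$labels)),
      labels_path, sep = "\t", quote = FALSE,
      row.names = FALSE, col.names = FALSE
    )
  }
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one pathway per line, `name TAB description TAB gene...`.
#' Pathway IDs are assigned by alphabetical order of the names regardless of
#' file order.
#'
#' @param path path to the GMT file.
#' @return a [pathway_collection()].
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stopf("empty GMT file: %s", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, 1L) < 3L)
  if (length(bad)) {
    stopf("GMT line %d has fewer than 3 fields (name, description, genes)",
          bad[1L])
  }
  nm <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(nm)) {
    stopf("duplicate pathway name(s) in GMT: %s",
          paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  desc <- vapply(fields, `[[`, "", 2L)
  sets <- lapply(fields, function(f) f[-(1:2)][nzchar(f[-(1:2)])])
  empty <- which(lengths(sets) == 0L)
  if (length(empty)) {
    stopf("GMT line %d ('%s') has an empty gene list", empty[1L], nm[empty[1L]])
  }
  names(sets) <- nm
  names(desc) <- nm
  pathway_collection(sets, descriptions = desc)
}

#' Write a pathway collection to GMT
#'
#' @param pathways a [pathway_collection()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_gmt <- function(pathways, path) {
  stopifnot(inherits(pathways, "pathway_collection"))
  desc <- pathways$descriptions
  desc[!nzchar(desc)] <- "na"
  lines <- vapply(seq_along(pathways$names), function(i) {
    paste(c(pathways$names[i], desc[i], pathways$genesets[[i]]),
          collapse = "\t")
  }, "")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a scored PPI edge list from TSV
#'
#' Expects three columns: gene A, gene B, confidence score. A header line is
#' tolerated (detected by a non-numeric third field on the first line).
#' STRING publishes combined scores on a 0-1000 scale; with
#' `score_scale = "string1000"` (the default) scores are divided by 1000.
#' Duplicate unordered pairs keep the maximum score; self-loops are dropped
#' with a warning giving the count.
#'
#' @param path path to the TSV file.
#' @param score_scale `"string1000"` (scores 0-1000, divided by 1000) or
#'   `"unit"` (scores already in `[0, 1]`).
#' @return a [ppi_network()].
#' @export
read_ppi_tsv <- function(path, score_scale = c("string1000", "unit")) {
  score_scale <- match.arg(score_scale)
  df <- utils::read.delim(path, header = FALSE, sep = "\t",
                          colClasses = "character", fill = FALSE)
  if (ncol(df) < 3L) stopf("PPI file needs 3 columns: geneA, geneB, score")
  if (is.na(suppressWarnings(as.numeric(df[1L, 3L])))) {
    df <- df[-1L, , drop = FALSE]  # header line
  }
  if (!nrow(df)) return(ppi_network())
  score <- suppressWarnings(as.numeric(df[[3L]]))
  if (anyNA(score)) stopf("non-numeric PPI score on line %d", which(is.na(score))[1L])
  if (any(score < 0)) stopf("negative PPI score on line %d", which(score < 0)[1L])
  if (score_scale == "string1000") {
    if (any(score > 1000)) stopf("score above 1000 under string1000 scale")
    score <- score / 1000
  } else if (any(score > 1)) {
    stopf("score above 1 under unit scale (line %d)", which(score > 1)[1L])
  }
  ppi_network(df[[1L]], df[[2L]], score)
}

#' Write a PPI network to a 3-column TSV (unit-scale scores)
#'
#' @param ppi a [ppi_network()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_ppi_tsv <- function(ppi, path) {
  stopifnot(inherits(ppi, "ppi_network"))
  utils::write.table(as.data.frame(ppi), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a pathway interaction network edge list to TSV
#'
#' Columns `id_a`, `id_b`, `name_a`, `name_b`, `weight`, sorted by
#' descending weight then ascending `(id_a, id_b)`. An empty network yields
#' a header-only file.
#'
#' @param pin a [build_pin()] result (`pathway_interaction_network`).
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_network_tsv <- function(pin, path) {
  stopifnot(inherits(pin, "pathway_interaction_network"))
  e <- pin$edges
  df <- data.frame(
    id_a = e$id_a, id_b = e$id_b,
    name_a = pin$pathway_names[e$id_a + 1L],
    name_b = pin$pathway_names[e$id_b + 1L],
    weight = e$weight,
    stringsAsFactors = FALSE
  )
  df <- df[order(-df$weight, df$id_a, df$id_b), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read a selection result as JSON
#'
#' The JSON carries the seed pathway and its statistic, the ordered selected
#' IDs, the mean-AUC trace, the final AUC and an optional configuration echo.
#'
#' @param result a `selection_result` (see [greedy_select()]).
#' @param path output path.
#' @param config optional list echoed into the JSON for provenance.
#' @return invisibly, `path`.
#' @export
write_results_json <- function(result, path, config = NULL) {
  stopifnot(inherits(result, "selection_result"))
  payload <- list(
    seed_id = result$seed_id,
    seed_statistic = result$seed_statistic,
    selected_ids = I(result$selected_ids),
    auc_trace = I(result$auc_trace),
    final_auc = result$final_auc,
    n_pathways = result$n_pathways
  )
  if (!is.null(config)) payload$config <- config
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_results_json
#' @return for `read_results_json`, the re-assembled `selection_result`.
#' @export
read_results_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  selection_result(
    seed_id = as.integer(x$seed_id),
    seed_statistic = as.numeric(x$seed_statistic),
    selected_ids = as.integer(x$selected_ids),
    auc_trace = as.numeric(x$auc_trace)
  )
}
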
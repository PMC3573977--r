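# Benchmark harness: coverage and average accuracy of the rating system at
# score cutoffs, against family/subgroup labels in the style of
# structure-function classification databases (family members share
# substrate specificity; subgroup members share catalytic machinery).

#' Per-query true positive rate
#'
#' The fraction of hits whose label matches the query's in the given
#' context: `"family"` requires the same family; `"subgroup"` also counts
#' hits from the same subgroup but a different family as true.
#'
#' @param query_id Protein ID of the query (must be labeled).
#' @param hit_ids Protein IDs of the hits under evaluation (non-empty).
#' @param labels `data.frame` with `protein_id`, `family`, `subgroup`.
#' @param context `"family"` or `"subgroup"`.
#' @return Rate in `[0, 1]`.
#' @export
true_positive_rate <- function(query_id, hit_ids, labels,
                               context = c("family", "subgroup")) {
  context <- match.arg(context)
  stopifnot(length(hit_ids) >= 1)
  lab <- function(ids) {
    idx <- match(ids, labels$protein_id)
    if (anyNA(idx)) {
      stop("unlabeled protein(s): ", paste(ids[is.na(idx)], collapse = ", "))
    }
    labels[idx, , drop = FALSE]
  }
  q <- lab(query_id)
  h <- lab(hit_ids)
  if (context == "family") {
    mean(h$family == q$family)
  } else {
    mean(h$subgroup == q$subgroup)
  }
}

#' Evaluate rating performance over labeled queries
#'
#' For each score cutoff `c`: coverage is the percentage of queries with at
#' least one scored hit at `>= c` (inclusive); family and subgroup accuracy
#' are the mean per-query true positive rates over exactly those covered
#' queries, computed on their hits scoring `>= c`. Queries with no hit at
#' the cutoff are excluded from the accuracy average, not counted as zero.
#'
#' @param per_query_results Named list: query `protein_id` to a
#'   `data.frame` with `subject_id` and `total` (rating score) columns; an
#'   empty `data.frame` means the query found nothing.
#' @param labels `data.frame` with `protein_id`, `family`, `subgroup`; every
#'   query and every counted hit must be labeled.
#' @param cutoffs Numeric vector of score cutoffs.
#' @return A `data.frame` with one row per cutoff: `cutoff`, `coverage`,
#'   `family_accuracy`, `subgroup_accuracy` (percentages; accuracies `NA`
#'   when coverage is zero).
#' @export
benchmark_evaluate <- function(per_query_results, labels,
                               cutoffs = c(6, 5, 4, 3)) {
  if (length(per_query_results) == 0) stop("empty query set")
  queries <- names(per_query_results)
  if (is.null(queries) || any(!nzchar(queries))) {
    stop("per_query_results must be named by query protein_id")
  }
  rows <- lapply(cutoffs, function(ct) {
    fam <- numeric(0); sub <- numeric(0)
    for (q in queries) {
      res <- per_query_results[[q]]
      keep <- res$total >= ct
      if (!any(keep)) next
      ids <- res$subject_id[keep]
      fam <- c(fam, true_positive_rate(q, ids, labels, "family"))
      sub <- c(sub, true_positive_rate(q, ids, labels, "subgroup"))
    }
    data.frame(
      cutoff = ct,
      coverage = 100 * length(fam) / length(queries),
      family_accuracy = if (length(fam)) 100 * mean(fam) else NA_real_,
      subgroup_accuracy = if (length(sub)) 100 * mean(sub) else NA_real_
    )
  })
  do.call(rbind, rows)
}
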
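# The plurality rating: four independent evidence features summed into a
# 0-6 score (1-6 for reference proteins, which always earn the reference
# point). Feature maxima are 2 (reciprocal search), 1.5 (MSC), 1.5
# (pairwise identity) and 1 (reference status).

RB_POINTS <- c(true = 1, false = 0, na = 0.25)

#' Score a reference candidate on the plurality rating scale
#'
#' Contributions:
#' \describe{
#'   \item{reciprocal search (max 2)}{per direction: best hit `"true"`
#'     gives +1, `"false"` 0, `"na"` (genome unresolvable) +0.25.}
#'   \item{MSC (max 1.5)}{+0.5 per identity cutoff at which the candidate
#'     is MSC-accepted (see [msc_evaluate()]).}
#'   \item{pairwise identity (max 1.5)}{+0.5 per threshold in
#'     `pairwise_thresholds` strictly exceeded by the query-vs-candidate
#'     identity; thresholds are cumulative, so 65% identity earns all of
#'     >60, >50, >40.}
#'   \item{reference status (max 1)}{+1 if the candidate is a reference
#'     protein. The pipeline only rates reference proteins, so pipeline
#'     scores range from 1 (when both genomes resolve) to 6; the function
#'     itself accepts `is_reference = FALSE` for library use.}
#' }
#' Points come in 0.25 granularity and are summed exactly, no rounding.
#'
#' @param verdict List with `q2h`, `h2q` in `"true"`/`"false"`/`"na"` (see
#'   [reciprocal_best_hit()]).
#' @param msc_result Result of [msc_evaluate()], or a logical vector of
#'   per-cutoff acceptances.
#' @param pairwise_identity Percent identity of the original
#'   query-vs-candidate hit.
#' @param is_reference Whether the candidate is a reference protein.
#' @param pairwise_thresholds Identity thresholds (%), each worth +0.5 when
#'   strictly exceeded.
#' @return A list with `rb_points`, `msc_points`, `pairwise_points`,
#'   `ref_point`, `total`.
#' @export
#' @examples
#' score_reference(list(q2h = "true", h2q = "true"),
#'                 c(TRUE, TRUE, TRUE), 70, TRUE)$total  # 6
score_reference <- function(verdict, msc_result, pairwise_identity,
                            is_reference,
                            pairwise_thresholds = c(60, 50, 40)) {
  stopifnot(verdict$q2h %in% names(RB_POINTS),
            verdict$h2q %in% names(RB_POINTS))
  accepted <- if (is.list(msc_result)) msc_result$accepted_at else msc_result
  rb <- unname(RB_POINTS[verdict$q2h] + RB_POINTS[verdict$h2q])
  msc <- 0.5 * sum(accepted)
  pairwise <- 0.5 * sum(pairwise_identity > pairwise_thresholds)
  ref <- if (isTRUE(is_reference)) 1 else 0
  list(rb_points = rb, msc_points = msc, pairwise_points = pairwise,
       ref_point = ref, total = rb + msc + pairwise + ref)
}

#' Rank scored reference candidates
#'
#' Orders candidates first by rating score (descending), second by
#' expectation value (ascending), then by subject ID (ascending) as a
#' deterministic tie-break, and assigns consecutive ranks from 1.
#'
#' @param scored `data.frame` of scored candidates with at least `total`,
#'   `e_value`, `subject_id` columns.
#' @return The same `data.frame`, sorted, with a `rank` column first.
#' @export
rank_results <- function(scored) {
  ord <- order(-scored$total, scored$e_value, scored$subject_id,
               method = "radix")
  out <- scored[ord, , drop = FALSE]
  out <- cbind(rank = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}

#' Filter ranked candidates for the detailed display
#'
#' Candidates scoring below `min_score` are distant homologs whose function
#' may have diverged; by default they are dropped from the detailed panel
#' (the rule discards scores strictly lower than 3, so a score of exactly 3
#' survives). Order is preserved; the unfiltered summary remains available
#' upstream.
#'
#' @param ranked Ranked `data.frame` from [rank_results()].
#' @param min_score Minimum retained rating score.
#' @return The filtered `data.frame`, order preserved.
#' @export
apply_display_filter <- function(ranked, min_score = 3) {
  out <- ranked[ranked$total >= min_score, , drop = FALSE]
  rownames(out) <- NULL
  out
}
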
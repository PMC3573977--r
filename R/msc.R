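# Multiple sequence comparison (MSC): instead of judging a reference
# protein by a single pairwise alignment to the query, compare it against
# the query's whole close sequence set and ask what fraction of the set it
# detects above an identity cutoff -- a more robust statistic for homology.

#' MSC parameters
#'
#' @param close_set_min_coverage Minimum query coverage (%) for a hit to
#'   enter the close sequence set.
#' @param close_set_max_evalue Maximum e-value for close-set membership.
#' @param close_set_cap Maximum close-set size; the best-sorted hits are
#'   kept.
#' @param hit_min_coverage Minimum coverage (%) of the reference (as query)
#'   for a close-set member to count as hit in the ratio.
#' @param ratio_threshold Acceptance threshold; acceptance requires the
#'   filtered hit ratio to be strictly greater than this.
#' @param identity_cutoffs Identity cutoffs (%) at which acceptance is
#'   assessed, highest first.
#' @return A list of class `msc_params`.
#' @export
msc_params <- function(close_set_min_coverage = 50,
                       close_set_max_evalue = 1e-3,
                       close_set_cap = 250,
                       hit_min_coverage = 50,
                       ratio_threshold = 0.8,
                       identity_cutoffs = c(60, 50, 40)) {
  stopifnot(close_set_cap >= 1, ratio_threshold >= 0, ratio_threshold <= 1,
            length(identity_cutoffs) >= 1)
  structure(list(close_set_min_coverage = close_set_min_coverage,
                 close_set_max_evalue = close_set_max_evalue,
                 close_set_cap = close_set_cap,
                 hit_min_coverage = hit_min_coverage,
                 ratio_threshold = ratio_threshold,
                 identity_cutoffs = identity_cutoffs),
            class = "msc_params")
}

#' Build the query's close sequence set
#'
#' Members are the query's search hits passing the close-set filters
#' (coverage and e-value), excluding the query's own record -- a reference
#' must not inflate its ratio by hitting the query itself -- and capped at
#' the best-sorted `close_set_cap` members. An empty close set is signalled
#' with a warning; downstream MSC ratios are then all zero.
#'
#' @param query_hits Hit `data.frame` from [search_all()] on the query.
#' @param query_id The query's own protein ID, excluded from membership.
#' @param msc A [msc_params()] object.
#' @return A list with `member_ids` (character) and `n` (set size).
#' @export
build_close_set <- function(query_hits, query_id, msc = msc_params()) {
  keep <- query_hits$query_coverage >= msc$close_set_min_coverage &
    query_hits$e_value <= msc$close_set_max_evalue &
    query_hits$subject_id != query_id
  ids <- head(query_hits$subject_id[keep], msc$close_set_cap)
  if (length(ids) == 0) {
    warning("close sequence set is empty; MSC ratios will be zero")
  }
  list(member_ids = ids, n = length(ids))
}

# align the reference against every close-set member once; returns a
# data.frame of per-member identity and reference-side coverage
msc_alignments <- function(reference, close_set, collection, params) {
  idx <- match(close_set$member_ids, collection$protein_id)
  if (anyNA(idx)) {
    stop("close-set member(s) missing from collection: ",
         paste(close_set$member_ids[is.na(idx)], collapse = ", "))
  }
  do.call(rbind, lapply(idx, function(i) {
    align_pair(reference, collection[i, , drop = FALSE], params)
  }))
}

#' Filtered hit ratio of a reference against the close set
#'
#' The reference is used as a query against a database consisting of
#' exactly the close-set members; members matched at `percent_identity >=
#' identity_cutoff` with coverage of the reference >= `hit_min_coverage`
#' count as hits, and the ratio is hits over the close-set size N.
#'
#' @param reference One-row sequence collection for the reference protein.
#' @param close_set Result of [build_close_set()].
#' @param collection Full sequence collection `data.frame`.
#' @param identity_cutoff Identity cutoff in percent.
#' @param params A [search_params()] object.
#' @param msc A [msc_params()] object.
#' @return The ratio, in `[0, 1]`; 0 for an empty close set.
#' @export
filtered_hit_ratio <- function(reference, close_set, collection,
                               identity_cutoff, params = search_params(),
                               msc = msc_params()) {
  if (close_set$n == 0) return(0)
  aln <- msc_alignments(reference, close_set, collection, params)
  sum(aln$percent_identity >= identity_cutoff &
        aln$query_coverage >= msc$hit_min_coverage) / close_set$n
}

#' Evaluate a reference protein by multiple sequence comparison
#'
#' Computes the filtered hit ratio at each configured identity cutoff
#' (sharing one set of alignments) and the acceptance decision at each:
#' accepted iff the ratio is strictly greater than `ratio_threshold`.
#' Ratios are monotone non-increasing in the cutoff by construction.
#'
#' @inheritParams filtered_hit_ratio
#' @return A list with `reference_id`, `ratio_at` (named numeric, one entry
#'   per cutoff) and `accepted_at` (named logical).
#' @export
msc_evaluate <- function(reference, close_set, collection,
                         params = search_params(), msc = msc_params()) {
  cutoffs <- msc$identity_cutoffs
  labels <- as.character(cutoffs)
  if (close_set$n == 0) {
    ratios <- setNames(rep(0, length(cutoffs)), labels)
  } else {
    aln <- msc_alignments(reference, close_set, collection, params)
    ok_cov <- aln$query_coverage >= msc$hit_min_coverage
    ratios <- setNames(vapply(cutoffs, function(ct) {
      sum(ok_cov & aln$percent_identity >= ct) / close_set$n
    }, numeric(1)), labels)
  }
  list(reference_id = reference$protein_id[1],
       ratio_at = ratios,
       accepted_at = setNames(ratios > msc$ratio_threshold, labels))
}
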
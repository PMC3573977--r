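# Orthology assessment: per-genome greedy identity preclustering (to absorb
# allelic variants of the same gene), automatic query-taxon detection, and
# cluster-aware reciprocal best hits with NA handling for unresolvable
# genomes.

#' Precluster a genome's proteins by identity
#'
#' Greedy incremental clustering in the style of CD-HIT: sequences are
#' processed longest first (ties keep input order); each sequence joins the
#' first existing cluster whose representative it matches at >=
#' `min_identity`% with >= `min_coverage`% coverage of the shorter of the
#' two sequences, otherwise it founds a new cluster with itself as
#' representative. Defaults (97% / 90%) are tuned to collapse variants of
#' the same gene -- alleles, single-residue polymorphisms -- so that
#' reciprocal-best-hit tests are not derailed by near-identical records.
#'
#' @param seqs Sequence collection `data.frame`, all one taxon.
#' @param params A [search_params()] object for the pairwise alignments.
#' @param min_identity,min_coverage Clustering thresholds in percent;
#'   coverage is of the shorter sequence.
#' @return A named character vector mapping `protein_id` to the cluster
#'   representative's `protein_id`; representatives map to themselves.
#' @export
precluster_genome <- function(seqs, params = search_params(),
                              min_identity = 97, min_coverage = 90) {
  if (nrow(seqs) == 0) return(setNames(character(0), character(0)))
  if (length(unique(seqs$taxon)) > 1) {
    stop("precluster_genome expects sequences from a single taxon")
  }
  ord <- order(-nchar(seqs$residues), seq_len(nrow(seqs)))
  seqs <- seqs[ord, , drop = FALSE]
  reps <- integer(0)  # row indices of representatives, in founding order
  assignment <- character(nrow(seqs))
  for (i in seq_len(nrow(seqs))) {
    placed <- FALSE
    for (r in reps) {
      st <- align_stats(seqs$residues[i], seqs$residues[r], params)
      shorter_cov <- if (nchar(seqs$residues[i]) <= nchar(seqs$residues[r]))
        st$cov_a else st$cov_b
      if (st$identity >= min_identity && shorter_cov >= min_coverage) {
        assignment[i] <- seqs$protein_id[r]
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps <- c(reps, i)
      assignment[i] <- seqs$protein_id[i]
    }
  }
  setNames(assignment, seqs$protein_id)
}

#' Detect the query's taxon from its hit list
#'
#' Scans the (already sorted) hits in order and returns the taxon of the
#' first hit with at least 97% identity and 90% query coverage whose subject
#' has a genome assignment; such a hit is close enough to be the query's own
#' gene (or an allele of it). Returns `"UNRESOLVED"` when no hit qualifies.
#' A user-supplied taxon always wins over detection.
#'
#' @param hits Hit `data.frame`, sorted per the [search_all()] contract.
#' @param genome_table `data.frame` with `protein_id`, `taxon`.
#' @param manual_taxon Optional user-specified taxon; returned as-is.
#' @param min_identity,min_coverage Detection thresholds in percent.
#' @return A taxon token, or `"UNRESOLVED"`.
#' @export
detect_query_taxon <- function(hits, genome_table, manual_taxon = NULL,
                               min_identity = 97, min_coverage = 90) {
  if (!is.null(manual_taxon)) return(manual_taxon)
  for (i in seq_len(nrow(hits))) {
    if (hits$percent_identity[i] >= min_identity &&
        hits$query_coverage[i] >= min_coverage) {
      j <- match(hits$subject_id[i], genome_table$protein_id)
      if (!is.na(j)) return(genome_table$taxon[j])
    }
  }
  "UNRESOLVED"
}

genome_members <- function(collection, genome_table, taxon) {
  ids <- genome_table$protein_id[genome_table$taxon == taxon]
  collection[collection$protein_id %in% ids, , drop = FALSE]
}

# cluster representative of an id; ids absent from the map are their own
# representative (singleton)
cluster_rep <- function(id, cluster_map) {
  if (!is.null(cluster_map) && id %in% names(cluster_map)) {
    cluster_map[[id]]
  } else {
    id
  }
}

# best hit of `record` within `genome` (excluding protein_ids in `exclude`);
# NULL when the genome contributes no sequences
best_hit_in_genome <- function(record, genome, params, exclude = character(0)) {
  genome <- genome[!genome$protein_id %in% exclude, , drop = FALSE]
  if (nrow(genome) == 0) return(NULL)
  # best hit is about rank, not significance: disable the e-value cutoff
  p <- params; p$e_value_cutoff <- Inf; p$max_hits <- 1
  hits <- search_all(record, genome, p)
  if (nrow(hits) == 0) return(NULL)
  hits[1, , drop = FALSE]
}

#' Cluster-aware reciprocal best hit between query and candidate
#'
#' Assesses orthology by reciprocal best hits, with best-hit equality tested
#' at the level of cluster representatives (see [precluster_genome()]) so
#' that allelic variants of the same gene do not produce false negatives.
#' Two directions are assessed independently:
#' \describe{
#'   \item{q2h}{search the query against the candidate's genome; `"true"`
#'     iff the top hit's representative equals the candidate's.}
#'   \item{h2q}{search the candidate against the query's genome; `"true"`
#'     iff the top hit's representative equals the query's representative in
#'     that genome -- the query itself when it is a member, otherwise its
#'     >= 97% identity / >= 90% coverage match there.}
#' }
#' A direction is `"na"` when the genome it needs is unresolvable: the query
#' taxon is `"UNRESOLVED"`, the taxon has no sequences, or the query cannot
#' be anchored in its stated genome.
#'
#' @param query One-row sequence collection.
#' @param candidate_id Protein ID of the candidate (must be in
#'   `collection`).
#' @param query_taxon Taxon of the query, or `"UNRESOLVED"`.
#' @param collection Full sequence collection `data.frame`.
#' @param genome_table `data.frame` with `protein_id`, `taxon`.
#' @param cluster_maps Named list of [precluster_genome()] maps, by taxon;
#'   missing entries are treated as all-singleton genomes.
#' @param params A [search_params()] object.
#' @return A list with elements `q2h` and `h2q`, each one of `"true"`,
#'   `"false"`, `"na"`.
#' @export
reciprocal_best_hit <- function(query, candidate_id, query_taxon,
                                collection, genome_table,
                                cluster_maps = list(),
                                params = search_params()) {
  ci <- match(candidate_id, collection$protein_id)
  if (is.na(ci)) stop("candidate sequence missing from collection: ",
                      candidate_id)
  candidate <- collection[ci, , drop = FALSE]
  ct_idx <- match(candidate_id, genome_table$protein_id)
  cand_taxon <- if (is.na(ct_idx)) NA_character_ else
    genome_table$taxon[ct_idx]

  # query -> candidate's genome
  q2h <- "na"
  if (!is.na(cand_taxon)) {
    genome <- genome_members(collection, genome_table, cand_taxon)
    # exclude only a record carrying the query's own id; a sequence-identical
    # record under a different id is a legitimate best hit
    top <- best_hit_in_genome(query, genome, params,
                              exclude = query$protein_id[1])
    if (!is.null(top)) {
      cm <- cluster_maps[[cand_taxon]]
      q2h <- if (identical(cluster_rep(top$subject_id, cm),
                           cluster_rep(candidate_id, cm))) "true" else "false"
    }
  }

  # candidate -> query's genome
  h2q <- "na"
  if (!identical(query_taxon, "UNRESOLVED") && !is.na(query_taxon)) {
    genome <- genome_members(collection, genome_table, query_taxon)
    if (nrow(genome) > 0) {
      cm <- cluster_maps[[query_taxon]]
      # the query's stand-in in its genome: itself if a member, else its
      # close (>=97%/>=90%) match there
      if (query$protein_id[1] %in% genome$protein_id) {
        query_rep <- cluster_rep(query$protein_id[1], cm)
      } else {
        anchor <- best_hit_in_genome(query, genome, params)
        query_rep <- if (!is.null(anchor) &&
                         anchor$percent_identity >= 97 &&
                         anchor$query_coverage >= 90)
          cluster_rep(anchor$subject_id, cm) else NA_character_
      }
      if (!is.na(query_rep)) {
        top <- best_hit_in_genome(candidate, genome, params,
                                  exclude = candidate_id)
        if (!is.null(top)) {
          h2q <- if (identical(cluster_rep(top$subject_id, cm), query_rep))
            "true" else "false"
        }
      }
    }
  }

  list(q2h = q2h, h2q = h2q)
}
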
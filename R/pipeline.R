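# End-to-end orchestration: detect homologs and reference proteins
# (step 1), evaluate each homologous relationship and rate, rank and report
# the candidates (step 2).

#' Run the full reference-protein pipeline
#'
#' Executes: homology search of the query against the collection;
#' identification of reference-protein candidates; query-taxon detection
#' (unless supplied); lazy per-genome preclustering; per-candidate
#' reciprocal best hits and multiple sequence comparison; plurality
#' scoring; ranking; display filtering; and report writing. Zero homologs
#' or zero candidates yield a valid empty result, not an error. The run is
#' fully deterministic: identical inputs give identical outputs.
#'
#' @param query One-row sequence collection (see [seq_records()] /
#'   [read_fasta()]).
#' @param collection Sequence collection `data.frame`.
#' @param annotations,publications,genome_table Sidecar tables (see
#'   [read_sidecar_tables()]).
#' @param params A [search_params()] object.
#' @param msc A [msc_params()] object.
#' @param manual_taxon Optional user-specified query taxon; bypasses
#'   detection.
#' @param min_display_score Display-filter threshold for the detailed
#'   panel.
#' @param out_dir Optional output directory; when given, writes
#'   `report.tsv` (full ranked summary), `report.html` (display-filtered
#'   detail), and `results.tsv` (machine-readable full table).
#' @param verbose Log stage-by-stage counts via [message()].
#' @return A list with `hits`, `candidates`, `query_taxon`, `ranked` (full
#'   scored table), and `displayed` (after the display filter).
#' @export
run_pipeline <- function(query, collection, annotations, publications,
                         genome_table, params = search_params(),
                         msc = msc_params(), manual_taxon = NULL,
                         min_display_score = 3, out_dir = NULL,
                         verbose = TRUE) {
  say <- function(...) if (verbose) message(sprintf(...))

  say("step 1.1: homology search against %d sequences", nrow(collection))
  hits <- search_all(query, collection, params)
  say("step 1.1: %d homologs detected", nrow(hits))
  if (nrow(hits) == 0) say("no homologs found; reporting an empty result")

  say("step 1.2: identifying reference proteins")
  candidates <- identify_references(hits, annotations, publications)
  say("step 1.2: %d reference-protein candidates", nrow(candidates))

  if (is.null(manual_taxon)) {
    query_taxon <- detect_query_taxon(hits, genome_table)
    say("step 2.0: query taxon detected as %s", query_taxon)
  } else {
    query_taxon <- manual_taxon
    say("step 2.0: query taxon set manually to %s (detection bypassed)",
        query_taxon)
  }

  # precluster only the genomes the reciprocal searches will touch
  cand_taxa <- genome_table$taxon[match(candidates$subject_id,
                                        genome_table$protein_id)]
  needed <- setdiff(unique(c(cand_taxa, query_taxon)),
                    c(NA_character_, "UNRESOLVED"))
  cluster_maps <- lapply(setNames(needed, needed), function(tx) {
    precluster_genome(genome_members(collection, genome_table, tx), params)
  })
  say("step 2.0: preclustered %d genome(s)", length(cluster_maps))

  close_set <- build_close_set(hits, query$protein_id[1], msc)
  say("step 2.1: close sequence set of %d member(s)", close_set$n)

  scored <- lapply(seq_len(nrow(candidates)), function(i) {
    cand <- candidates[i, , drop = FALSE]
    ref_seq <- collection[match(cand$subject_id,
                                collection$protein_id), , drop = FALSE]
    verdict <- reciprocal_best_hit(query, cand$subject_id, query_taxon,
                                   collection, genome_table, cluster_maps,
                                   params)
    msc_res <- msc_evaluate(ref_seq, close_set, collection, params, msc)
    brk <- score_reference(verdict, msc_res, cand$percent_identity,
                           is_reference = TRUE)
    pub_ids <- cand$pubmed_ids[[1]]
    pub_str <- if (length(pub_ids) > 0) {
      paste(sort_publications(pub_ids, publications)$pmid, collapse = ";")
    } else ""
    data.frame(
      subject_id = cand$subject_id,
      description = cand$description,
      total = brk$total, rb_points = brk$rb_points,
      msc_points = brk$msc_points, pairwise_points = brk$pairwise_points,
      ref_point = brk$ref_point,
      q2h = verdict$q2h, h2q = verdict$h2q,
      msc_ratios = paste(sprintf("%g", msc_res$ratio_at), collapse = ";"),
      e_value = cand$e_value, percent_identity = cand$percent_identity,
      query_coverage = cand$query_coverage,
      sources = paste(cand$sources[[1]], collapse = ","),
      pubmed_ids = pub_str,
      stringsAsFactors = FALSE
    )
  })
  scored <- if (length(scored) > 0) do.call(rbind, scored) else
    data.frame(subject_id = character(0), description = character(0),
               total = numeric(0), rb_points = numeric(0),
               msc_points = numeric(0), pairwise_points = numeric(0),
               ref_point = numeric(0), q2h = character(0),
               h2q = character(0), msc_ratios = character(0),
               e_value = numeric(0), percent_identity = numeric(0),
               query_coverage = numeric(0), sources = character(0),
               pubmed_ids = character(0), stringsAsFactors = FALSE)

  ranked <- rank_results(scored)
  displayed <- apply_display_filter(ranked, min_display_score)
  say("step 2.2: %d candidate(s) rated; %d at or above display score %.4g",
      nrow(ranked), nrow(displayed), min_display_score)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_report(ranked, file.path(out_dir, "report.tsv"), "tsv")
    write_report(displayed, file.path(out_dir, "report.html"), "html")
    write.table(ranked, file.path(out_dir, "results.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    say("reports written to %s", out_dir)
  }

  list(hits = hits, candidates = candidates, query_taxon = query_taxon,
       ranked = ranked, displayed = displayed)
}
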
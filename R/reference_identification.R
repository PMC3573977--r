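# Flag which homologs are reference proteins -- experimentally studied,
# structurally characterized, or manually curated -- and attach evidence.

#' Identify reference proteins among search hits
#'
#' A hit is a reference-protein candidate when it has at least one evidence
#' source: (1) PubMed literature links, (2) a structure entry (PDB flag), or
#' (3) a curated record (Swiss-Prot flag). Publications linked to more than
#' `max_publication_size` protein records -- typically large-scale genome or
#' proteome studies that carry no per-protein functional insight -- are
#' dropped per publication before the PubMed source is assessed, so a
#' protein keeps its specific publications even when a mega-study link is
#' discarded. Hits without an annotation record are treated as unannotated.
#' Input hit order is preserved; the output is always a subset of the input.
#'
#' @param hits Hit `data.frame` from [search_all()] or [read_hit_table()].
#' @param annotations Annotation `data.frame` (see [read_sidecar_tables()]).
#' @param publications Publication `data.frame` with `pmid`, `date`,
#'   `n_linked_proteins`.
#' @param max_publication_size Exclusion threshold; a publication is kept
#'   iff `n_linked_proteins <= max_publication_size` (strictly more than the
#'   threshold is excluded).
#' @return A candidate `data.frame`: the surviving hit rows plus list-columns
#'   `sources` (subset of `"pubmed"`, `"pdb"`, `"swissprot"`) and
#'   `pubmed_ids` (surviving IDs), and a `description` column.
#' @export
identify_references <- function(hits, annotations, publications,
                                max_publication_size = 100) {
  if (nrow(hits) == 0) {
    out <- hits
    out$sources <- list(); out$pubmed_ids <- list()
    out$description <- character(0)
    return(out)
  }
  big <- publications$pmid[publications$n_linked_proteins >
                             max_publication_size]
  idx <- match(hits$subject_id, annotations$protein_id)
  sources <- vector("list", nrow(hits))
  pmids <- vector("list", nrow(hits))
  desc <- character(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    if (is.na(idx[i])) {  # unannotated: never an error, never a candidate
      sources[[i]] <- character(0); pmids[[i]] <- character(0)
      next
    }
    ann <- annotations[idx[i], ]
    keep <- setdiff(ann$pubmed_ids[[1]], big)
    src <- c(if (length(keep) > 0) "pubmed",
             if (isTRUE(ann$in_pdb)) "pdb",
             if (isTRUE(ann$in_swissprot)) "swissprot")
    # src may be NULL; [[<- NULL would delete the element, so wrap in list()
    sources[i] <- list(if (is.null(src)) character(0) else src)
    pmids[[i]] <- keep
    desc[i] <- ann$description
  }
  keep_row <- lengths(sources) > 0
  out <- hits[keep_row, , drop = FALSE]
  out$sources <- sources[keep_row]
  out$pubmed_ids <- pmids[keep_row]
  out$description <- desc[keep_row]
  rownames(out) <- NULL
  out
}

#' Sort publications for display
#'
#' Publications attached to a reference protein are shown newest first (the
#' most recent experimental characterization is usually the most
#' informative); ties on date break by ascending PubMed ID.
#'
#' @param pubmed_ids Character vector of PubMed IDs (all resolvable).
#' @param publications Publication `data.frame`.
#' @return The matching publication rows, ordered.
#' @export
sort_publications <- function(pubmed_ids, publications) {
  idx <- match(pubmed_ids, publications$pmid)
  if (anyNA(idx)) {
    stop("unknown pmid(s): ", paste(pubmed_ids[is.na(idx)], collapse = ", "))
  }
  sel <- publications[idx, , drop = FALSE]
  sel <- sel[order(sel$date, sel$pmid, method = "radix",
                   decreasing = c(TRUE, FALSE)), , drop = FALSE]
  rownames(sel) <- NULL
  sel
}
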
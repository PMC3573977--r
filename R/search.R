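# Homology search: a built-in Smith-Waterman backend plus an adapter to an
# external BLAST+ executable, both honouring the same hit-table contract.

#' Search parameters
#'
#' @param e_value_cutoff Maximum expectation value for a hit to be reported.
#' @param max_hits Maximum number of hits returned by [search_all()].
#' @param matrix_name Substitution matrix (any matrix shipped with
#'   Biostrings, e.g. `"BLOSUM62"`, `"BLOSUM45"`, `"PAM250"`).
#' @param gap_open Gap opening penalty (positive; a gap of length L costs
#'   `gap_open + L * gap_extend`, the BLAST convention).
#' @param gap_extend Gap extension penalty per gapped position.
#' @return A list of class `search_params`.
#' @export
search_params <- function(e_value_cutoff = 1e-3, max_hits = 500,
                          matrix_name = "BLOSUM62", gap_open = 11,
                          gap_extend = 1) {
  stopifnot(e_value_cutoff >= 0, max_hits >= 1, gap_open > 0,
            gap_extend > 0, gap_extend <= gap_open)
  structure(list(e_value_cutoff = e_value_cutoff, max_hits = max_hits,
                 matrix_name = matrix_name, gap_open = gap_open,
                 gap_extend = gap_extend),
            class = "search_params")
}

# Karlin-Altschul constants for ungapped BLOSUM62 statistics; applied to
# gapped scores as a documented approximation -- monotone in raw score,
# which is all the pipeline needs (ranking ties, close-set e-value filter).
KA_LAMBDA <- 0.318
KA_K <- 0.13

.matrix_cache <- new.env(parent = emptyenv())

substitution_matrix <- function(name) {
  if (!is.null(.matrix_cache[[name]])) return(.matrix_cache[[name]])
  available <- data(package = "Biostrings")$results[, "Item"]
  if (!name %in% available) stop("unknown substitution matrix: ", name)
  e <- new.env()
  data(list = name, package = "Biostrings", envir = e)
  .matrix_cache[[name]] <- get(name, envir = e)
  .matrix_cache[[name]]
}

karlin_altschul <- function(raw_score, m, n) {
  bit <- (KA_LAMBDA * raw_score - log(KA_K)) / log(2)
  list(bit_score = bit, e_value = m * n * 2^(-bit))
}

# core alignment statistics for one ordered pair; identity denominator is the
# alignment length including gaps, coverage the aligned span over the full
# sequence, per side
align_stats <- function(res_a, res_b, params) {
  mat <- substitution_matrix(params$matrix_name)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(res_a), Biostrings::AAString(res_b),
    type = "local", substitutionMatrix = mat,
    gapOpening = params$gap_open, gapExtension = params$gap_extend
  )
  raw <- Biostrings::score(aln)
  m <- nchar(res_a); n <- nchar(res_b)
  if (raw <= 0 || Biostrings::nchar(aln) == 0) {
    # no positive-scoring local alignment: empty alignment at score zero
    return(list(identity = 0, cov_a = 0, cov_b = 0, aln_length = 0L,
                raw_score = 0, bit_score = (-log(KA_K)) / log(2),
                e_value = m * n))
  }
  p <- Biostrings::pattern(aln); s <- Biostrings::subject(aln)
  ka <- karlin_altschul(raw, m, n)
  list(
    identity = 100 * Biostrings::nmatch(aln) / Biostrings::nchar(aln),
    cov_a = 100 * (Biostrings::end(p) - Biostrings::start(p) + 1) / m,
    cov_b = 100 * (Biostrings::end(s) - Biostrings::start(s) + 1) / n,
    aln_length = Biostrings::nchar(aln),
    raw_score = raw,
    bit_score = ka$bit_score,
    e_value = ka$e_value
  )
}

#' Align a query against one subject sequence
#'
#' Smith-Waterman local alignment under the named substitution matrix with
#' affine gap penalties. Percent identity is `100 * identities /
#' alignment_length` (gaps included in the denominator); query coverage is
#' the aligned query span over the full query length. Bit score and e-value
#' follow Karlin-Altschul statistics, `bit = (lambda * S - ln K) / ln 2` and
#' `E = m * n * 2^(-bit)`, with the ungapped BLOSUM62 constants
#' `lambda = 0.318`, `K = 0.13` applied to the gapped score -- a deliberate
#' approximation that preserves score order. When no residue pair scores
#' positively the empty alignment is reported: identity 0, coverage 0,
#' `E >= m * n`.
#'
#' @param a Query: one-row sequence collection (see [seq_records()]).
#' @param b Subject, same form.
#' @param params A [search_params()] object.
#' @return A one-row hit `data.frame` (columns as in [read_hit_table()]).
#' @export
#' @examples
#' q <- seq_records("q", "MKVLA")
#' align_pair(q, q)$percent_identity  # 100
align_pair <- function(a, b, params = search_params()) {
  stopifnot(nzchar(a$residues[1]), nzchar(b$residues[1]))
  st <- align_stats(a$residues[1], b$residues[1], params)
  data.frame(
    query_id = a$protein_id[1], subject_id = b$protein_id[1],
    percent_identity = st$identity, query_coverage = st$cov_a,
    e_value = st$e_value, bit_score = st$bit_score,
    aln_length = st$aln_length, stringsAsFactors = FALSE
  )
}

# sort per the search contract: ascending e-value, ties by descending bit
# score, then ascending subject_id (C locale for determinism)
sort_hits <- function(hits) {
  ord <- order(hits$e_value, -hits$bit_score, hits$subject_id,
               method = "radix")
  hits[ord, , drop = FALSE]
}

#' Search a query against a local sequence collection
#'
#' Aligns the query against every collection sequence with [align_pair()],
#' keeps hits with `e_value <= e_value_cutoff`, sorts by ascending e-value
#' (ties: descending bit score, then ascending subject id) and truncates to
#' `max_hits`. The query's own record, if present in the collection, is a
#' legitimate hit. Deterministic: identical inputs give identical output.
#'
#' @param query One-row sequence collection.
#' @param db Sequence collection `data.frame` (non-empty).
#' @param params A [search_params()] object.
#' @return A hit `data.frame`, possibly zero-row.
#' @export
search_all <- function(query, db, params = search_params()) {
  stopifnot(nrow(db) >= 1)
  hits <- do.call(rbind, lapply(seq_len(nrow(db)), function(i) {
    align_pair(query, db[i, , drop = FALSE], params)
  }))
  hits <- hits[hits$e_value <= params$e_value_cutoff, , drop = FALSE]
  if (nrow(hits) == 0) return(empty_hits())
  hits <- sort_hits(hits)
  hits <- head(hits, params$max_hits)
  rownames(hits) <- NULL
  hits
}

#' Search with an external BLAST+ executable
#'
#' Shells out to `blastp` (or a compatible executable) with tabular output
#' `-outfmt "6 std qlen slen"`, parses the result via [read_hit_table()],
#' and applies the same cutoff/sort/truncate contract as [search_all()].
#'
#' @param query One-row sequence collection.
#' @param db_path Path to a formatted BLAST database (see `makeblastdb`).
#' @param params A [search_params()] object.
#' @param executable Name or path of the BLAST executable.
#' @return A hit `data.frame`.
#' @export
external_search <- function(query, db_path, params = search_params(),
                            executable = "blastp") {
  if (Sys.which(executable) == "") {
    stop("external search executable '", executable, "' not found on PATH; ",
         "use the built-in backend (search_all) instead")
  }
  qfile <- tempfile(fileext = ".fasta")
  ofile <- tempfile(fileext = ".tsv")
  on.exit(unlink(c(qfile, ofile)), add = TRUE)
  write_fasta(query, qfile)
  status <- system2(executable, c(
    "-query", qfile, "-db", db_path,
    "-evalue", format(params$e_value_cutoff, scientific = TRUE),
    "-matrix", params$matrix_name,
    "-gapopen", params$gap_open, "-gapextend", params$gap_extend,
    "-max_target_seqs", params$max_hits,
    "-outfmt", shQuote("6 std qlen slen"), "-out", ofile
  ), stdout = FALSE, stderr = FALSE)
  if (status != 0) stop(executable, " exited with status ", status)
  hits <- read_hit_table(ofile)
  # one HSP per subject: keep the best-sorted one
  hits <- sort_hits(hits)
  hits <- hits[!duplicated(hits$subject_id), , drop = FALSE]
  hits <- hits[hits$e_value <= params$e_value_cutoff, , drop = FALSE]
  hits <- head(hits, params$max_hits)
  rownames(hits) <- NULL
  hits
}
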
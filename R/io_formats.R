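# Readers and writers: FASTA sequences, BLAST-tabular hit tables, the three
# TSV sidecar tables (annotation links, publications, genome membership), and
# the ranked report.

VALID_RESIDUES <- "ACDEFGHIKLMNPQRSTVWYX"

#' Construct a sequence record table
#'
#' Sequence collections are plain data frames with one row per protein and
#' columns `protein_id`, `description`, `taxon`, `residues`. This helper
#' builds one from parallel vectors, applying the same validation as
#' [read_fasta()].
#'
#' @param protein_id Character vector of unique identifiers.
#' @param residues Character vector of amino-acid strings (20 standard
#'   letters plus `X`; lower case accepted and upcased).
#' @param taxon Taxon token per sequence, `"UNKNOWN"` when unassigned.
#' @param description Free-text description per sequence.
#' @return A `data.frame` with columns `protein_id`, `description`, `taxon`,
#'   `residues`.
#' @export
#' @examples
#' seq_records("p1", "MKVLA", taxon = "ecoli")
seq_records <- function(protein_id, residues, taxon = "UNKNOWN",
                        description = "") {
  protein_id <- as.character(protein_id)
  residues <- toupper(as.character(residues))
  if (length(protein_id) != length(residues)) {
    stop("protein_id and residues must have equal length")
  }
  if (any(!nzchar(protein_id))) stop("empty protein_id")
  dup <- protein_id[duplicated(protein_id)]
  if (length(dup) > 0) {
    stop("duplicate protein_id: ", paste(unique(dup), collapse = ", "))
  }
  residues <- sub("\\*$", "", residues)       # trailing stop codon
  residues <- gsub("-", "", residues, fixed = TRUE)  # alignment gaps
  bad <- grepl(sprintf("[^%s]", VALID_RESIDUES), residues)
  if (any(bad)) {
    stop("invalid residue characters in: ",
         paste(protein_id[bad], collapse = ", "))
  }
  if (any(!nzchar(residues))) {
    stop("zero-length sequence for: ",
         paste(protein_id[!nzchar(residues)], collapse = ", "))
  }
  data.frame(
    protein_id = protein_id,
    description = rep_len(as.character(description), length(protein_id)),
    taxon = rep_len(as.character(taxon), length(protein_id)),
    residues = residues,
    stringsAsFactors = FALSE
  )
}

#' Read protein sequences from a FASTA file
#'
#' The first whitespace-delimited token of each header is the `protein_id`;
#' the remainder is the description. A `taxon=<token>` key anywhere in the
#' description assigns the sequence to a genome, otherwise the taxon is
#' `"UNKNOWN"`. Residues are uppercased; a trailing `*` is stripped and gap
#' characters (`-`) are removed; any other non-amino-acid character is an
#' error, as are duplicate IDs and empty files.
#'
#' @param path Path to a FASTA file.
#' @return A sequence collection `data.frame` (see [seq_records()]).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) stop("empty FASTA file: ", path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  taxon <- rep("UNKNOWN", length(ids))
  has_tax <- grepl("taxon=\\S+", desc)
  taxon[has_tax] <- sub(".*taxon=(\\S+).*", "\\1", desc[has_tax])
  seq_records(ids, as.character(set), taxon = taxon, description = desc)
}

#' Write a sequence collection to FASTA
#'
#' Headers carry the `protein_id`, a `taxon=` key (when not `"UNKNOWN"`), and
#' the description; [read_fasta()] on the output recovers `protein_id`,
#' `residues` and `taxon` exactly.
#'
#' @param seqs Sequence collection `data.frame`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  tax <- ifelse(seqs$taxon == "UNKNOWN", "", paste0(" taxon=", seqs$taxon))
  desc <- ifelse(nzchar(seqs$description) &
                   !grepl("taxon=", seqs$description),
                 paste0(" ", seqs$description), "")
  lines <- as.vector(rbind(paste0(">", seqs$protein_id, tax, desc),
                           seqs$residues))
  writeLines(lines, path)
  invisible(path)
}

# zero-row hit table with the canonical column set
empty_hits <- function() {
  data.frame(
    query_id = character(0), subject_id = character(0),
    percent_identity = numeric(0), query_coverage = numeric(0),
    e_value = numeric(0), bit_score = numeric(0),
    aln_length = integer(0), stringsAsFactors = FALSE
  )
}

#' Read a BLAST tabular hit table
#'
#' Accepts the standard 12-column tab-separated format (`outfmt 6`:
#' qseqid sseqid pident length mismatch gapopen qstart qend sstart send
#' evalue bitscore) or a 14-column extension appending `qlen` and `slen`.
#' Query coverage is computed as `100 * (qend - qstart + 1) / qlen`
#' (coordinates 1-based inclusive); a 12-column file carries no `qlen`, so
#' coverage is underivable and the reader errors. Row order is preserved.
#'
#' @param path Path to the tabular file.
#' @return A hit `data.frame` with columns `query_id`, `subject_id`,
#'   `percent_identity`, `query_coverage`, `e_value`, `bit_score`,
#'   `aln_length`.
#' @export
read_hit_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) return(empty_hits())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(fields)
  bad <- which(!(ncols %in% c(12L, 14L)))
  if (length(bad) > 0) {
    stop("malformed hit-table row at line ", bad[1],
         ": expected 12 or 14 tab-separated columns, got ", ncols[bad[1]])
  }
  if (any(ncols == 12L)) {
    stop("coverage underivable: 12-column hit table at line ",
         which(ncols == 12L)[1],
         " lacks qlen; supply the 14-column dialect with qlen and slen")
  }
  num <- function(i, name) {
    v <- suppressWarnings(as.numeric(vapply(fields, `[`, "", i)))
    if (anyNA(v)) {
      stop("malformed hit-table row at line ", which(is.na(v))[1],
           ": non-numeric ", name)
    }
    v
  }
  qstart <- num(7, "qstart"); qend <- num(8, "qend"); qlen <- num(13, "qlen")
  if (any(qlen < 1)) stop("malformed hit-table: qlen < 1")
  data.frame(
    query_id = vapply(fields, `[`, "", 1),
    subject_id = vapply(fields, `[`, "", 2),
    percent_identity = num(3, "pident"),
    query_coverage = 100 * (qend - qstart + 1) / qlen,
    e_value = num(11, "evalue"),
    bit_score = num(12, "bitscore"),
    aln_length = as.integer(num(4, "length")),
    stringsAsFactors = FALSE
  )
}

#' Write a hit table in the 14-column BLAST tabular dialect
#'
#' Companion writer to [read_hit_table()]; emits alignment coordinates that
#' reproduce the stored `query_coverage` when re-read (span starting at
#' position 1). Intended for caching search results between runs.
#'
#' @param hits Hit `data.frame`.
#' @param path Output path.
#' @param qlen,slen Query/subject lengths; `qlen` is required to make
#'   coverage round-trip, recycled as needed.
#' @return `path`, invisibly.
#' @export
write_hit_table <- function(hits, path, qlen, slen = qlen) {
  qlen <- rep_len(qlen, nrow(hits))
  slen <- rep_len(slen, nrow(hits))
  qend <- round(hits$query_coverage * qlen / 100)
  rows <- sprintf("%s\t%s\t%.3f\t%d\t0\t0\t1\t%d\t1\t%d\t%g\t%.1f\t%d\t%d",
                  hits$query_id, hits$subject_id, hits$percent_identity,
                  hits$aln_length, qend, hits$aln_length, hits$e_value,
                  hits$bit_score, qlen, slen)
  writeLines(rows, path)
  invisible(path)
}

#' Read the three annotation sidecar tables
#'
#' The tables stand in for a pre-processed local copy of the cross-links a
#' sequence database maintains between proteins, literature and curated
#' resources:
#' \describe{
#'   \item{links}{`protein_id`, `pubmed_ids` (semicolon-joined, may be
#'     empty), `in_swissprot` (0/1), `in_pdb` (0/1), `description`.}
#'   \item{pubs}{`pmid`, `date` (YYYY-MM-DD), `n_linked_proteins` (count of
#'     protein records the publication is linked to, database-wide).}
#'   \item{genomes}{`protein_id`, `taxon`.}
#' }
#' Every PubMed ID cited in links must exist in pubs; a protein may appear
#' under at most one taxon.
#'
#' @param links_path,pubs_path,genomes_path Paths to the TSV files.
#' @return A list with elements `annotations` (data frame with a list-column
#'   `pubmed_ids`), `publications` (`pmid`, `date` as `Date`,
#'   `n_linked_proteins`), and `genome_table` (`protein_id`, `taxon`).
#' @export
read_sidecar_tables <- function(links_path, pubs_path, genomes_path) {
  read_tsv <- function(path, required) {
    if (!file.exists(path)) stop("no such file: ", path)
    df <- read.delim(path, sep = "\t", header = TRUE,
                     colClasses = "character", check.names = FALSE,
                     quote = "", comment.char = "")
    missing <- setdiff(required, names(df))
    if (length(missing) > 0) {
      stop("missing column(s) in ", basename(path), ": ",
           paste(missing, collapse = ", "))
    }
    df
  }
  links <- read_tsv(links_path, c("protein_id", "pubmed_ids", "in_swissprot",
                                  "in_pdb", "description"))
  pubs <- read_tsv(pubs_path, c("pmid", "date", "n_linked_proteins"))
  genomes <- read_tsv(genomes_path, c("protein_id", "taxon"))

  dates <- as.Date(pubs$date, format = "%Y-%m-%d")
  if (anyNA(dates)) {
    stop("unparseable date in pubs table: ",
         paste(pubs$date[is.na(dates)], collapse = ", "))
  }
  n_linked <- as.integer(pubs$n_linked_proteins)
  if (anyNA(n_linked) || any(n_linked < 1)) {
    stop("n_linked_proteins must be a positive integer")
  }
  publications <- data.frame(pmid = pubs$pmid, date = dates,
                             n_linked_proteins = n_linked,
                             stringsAsFactors = FALSE)
  if (anyDuplicated(publications$pmid)) stop("duplicate pmid in pubs table")

  pmid_sets <- lapply(strsplit(links$pubmed_ids, ";", fixed = TRUE),
                      function(x) x[nzchar(x)])
  dangling <- setdiff(unique(unlist(pmid_sets)), publications$pmid)
  if (length(dangling) > 0) {
    stop("links table cites unknown pmid(s): ",
         paste(dangling, collapse = ", "))
  }
  annotations <- data.frame(protein_id = links$protein_id,
                            stringsAsFactors = FALSE)
  annotations$pubmed_ids <- pmid_sets
  annotations$in_swissprot <- links$in_swissprot %in% c("1", "TRUE", "true")
  annotations$in_pdb <- links$in_pdb %in% c("1", "TRUE", "true")
  annotations$description <- links$description
  if (anyDuplicated(annotations$protein_id)) {
    stop("duplicate protein_id in links table")
  }

  if (anyDuplicated(genomes$protein_id)) {
    stop("protein assigned to more than one taxon: ",
         paste(unique(genomes$protein_id[duplicated(genomes$protein_id)]),
               collapse = ", "))
  }
  list(annotations = annotations, publications = publications,
       genome_table = genomes[, c("protein_id", "taxon")])
}

REPORT_COLUMNS <- c("rank", "subject_id", "description", "rating_score",
                    "e_value", "percent_identity", "query_coverage",
                    "sources", "pubmed_ids")

# flatten a ranked-references data frame into display columns; the writer
# never re-sorts -- row order is the caller's contract
report_rows <- function(ranked) {
  data.frame(
    rank = ranked$rank,
    subject_id = ranked$subject_id,
    description = ranked$description,
    rating_score = sprintf("%.2f", ranked$total),
    e_value = format(ranked$e_value, digits = 6, scientific = TRUE,
                     trim = TRUE),
    percent_identity = sprintf("%.1f", ranked$percent_identity),
    query_coverage = sprintf("%.1f", ranked$query_coverage),
    sources = ranked$sources,
    pubmed_ids = ranked$pubmed_ids,
    stringsAsFactors = FALSE
  )
}

#' Write the ranked reference-protein report
#'
#' TSV output is a summary table with columns `rank`, `subject_id`,
#' `description`, `rating_score` (two decimals), `e_value`,
#' `percent_identity`, `query_coverage`, `sources` (comma-joined subset of
#' `pubmed`, `pdb`, `swissprot`) and `pubmed_ids` (semicolon-joined,
#' date-sorted). HTML output renders the same table plus a per-protein
#' detail block with the rating breakdown. The writer preserves the input
#' row order: ranking and display filtering happen upstream
#' ([rank_results()], [apply_display_filter()]).
#'
#' @param ranked Ranked references `data.frame` from [rank_results()].
#' @param path Output path.
#' @param format `"tsv"` or `"html"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(ranked, path, format = c("tsv", "html")) {
  format <- match.arg(format)
  rows <- report_rows(ranked)
  if (format == "tsv") {
    write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = TRUE)
    return(invisible(path))
  }
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  html <- c("<!DOCTYPE html>", "<html><head><meta charset='utf-8'>",
            "<title>Ranked reference proteins</title></head><body>",
            "<h1>Ranked reference proteins</h1>",
            "<table border='1'><tr>",
            paste0("<th>", REPORT_COLUMNS, "</th>"), "</tr>")
  for (i in seq_len(nrow(rows))) {
    html <- c(html, "<tr>",
              paste0("<td>", esc(unlist(rows[i, REPORT_COLUMNS])), "</td>"),
              "</tr>")
  }
  html <- c(html, "</table>", "<h2>Rating details</h2>")
  for (i in seq_len(nrow(ranked))) {
    html <- c(html, sprintf(
      paste0("<div class='detail'><h3>%s</h3><ul>",
             "<li>reciprocal search: %.2f</li>",
             "<li>multiple sequence comparison: %.2f</li>",
             "<li>pairwise identity: %.2f</li>",
             "<li>reference status: %.2f</li>",
             "<li>total: %.2f</li></ul></div>"),
      esc(ranked$subject_id[i]), ranked$rb_points[i], ranked$msc_points[i],
      ranked$pairwise_points[i], ranked$ref_point[i], ranked$total[i]))
  }
  html <- c(html, "</body></html>")
  writeLines(html, path)
  invisible(path)
}
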
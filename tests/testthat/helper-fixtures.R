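# Shared test fixtures, generated in code and cached per test run.

default_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_fixture(fixture_config(seed = 42))
    }
    cache
  }
})

random_protein <- function(len, seed) {
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  set.seed(seed)
  paste(sample(aa, len, replace = TRUE), collapse = "")
}

# minimal scored-candidates frame for ranking/report tests
make_scored <- function(subject_id, total, e_value = 1e-20,
                        description = "protein") {
  n <- length(subject_id)
  data.frame(
    subject_id = subject_id,
    description = rep_len(description, n),
    total = total,
    rb_points = rep_len(0, n), msc_points = rep_len(0, n),
    pairwise_points = rep_len(0, n), ref_point = rep_len(1, n),
    e_value = rep_len(e_value, n),
    percent_identity = rep_len(90, n), query_coverage = rep_len(100, n),
    sources = rep_len("pubmed", n), pubmed_ids = rep_len("PM0001", n),
    stringsAsFactors = FALSE
  )
}

write_lines_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# sidecar table trio written to tempfiles; returns the three paths
write_sidecars <- function(links_rows, pubs_rows, genome_rows) {
  list(
    links = write_lines_tmp(c(
      "protein_id\tpubmed_ids\tin_swissprot\tin_pdb\tdescription",
      links_rows), ".tsv"),
    pubs = write_lines_tmp(c(
      "pmid\tdate\tn_linked_proteins", pubs_rows), ".tsv"),
    genomes = write_lines_tmp(c(
      "protein_id\ttaxon", genome_rows), ".tsv")
  )
}
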
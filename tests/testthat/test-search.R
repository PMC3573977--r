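test_that("self-alignment gives full identity and coverage", {
  for (res in c("MKVLA", random_protein(60, seed = 11))) {
    x <- seq_records("x", res)
    hit <- align_pair(x, x)
    expect_equal(hit$percent_identity, 100)
    expect_equal(hit$query_coverage, 100)
  }
})

test_that("a single central substitution yields 4/5 identity", {
  hit <- align_pair(seq_records("a", "MKVLA"), seq_records("b", "MKALA"))
  expect_equal(hit$percent_identity, 80)
  expect_equal(hit$aln_length, 5L)
})

test_that("no positive-scoring pair reports the empty alignment", {
  a <- seq_records("a", "WWWWW")
  b <- seq_records("b", "PPPPP")
  expect_equal(sw_score_oracle("WWWWW", "PPPPP"), 0)  # oracle confirms
  hit <- align_pair(a, b, search_params(e_value_cutoff = Inf))
  expect_equal(hit$percent_identity, 0)
  expect_equal(hit$query_coverage, 0)
  expect_gte(hit$e_value, 25)  # m * n * 2^0
})

test_that("alignment scores match the exhaustive DP oracle on short pairs", {
  set.seed(101)
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  for (i in 1:12) {
    la <- sample(5:30, 1); lb <- sample(5:30, 1)
    a <- paste(sample(aa, la, replace = TRUE), collapse = "")
    # half the pairs are related (mutated copies), half independent
    b <- if (i %% 2 == 0) mutate_sequence(a, 70) else
      paste(sample(aa, lb, replace = TRUE), collapse = "")
    st <- refrank:::align_stats(a, b, search_params())
    expect_equal(st$raw_score, sw_score_oracle(a, b),
                 info = sprintf("pair %d", i))
  }
})

test_that("percent identity is symmetric", {
  set.seed(202)
  base <- random_protein(80, seed = 33)
  others <- c(mutate_sequence(base, 90), mutate_sequence(base, 55),
              random_protein(80, seed = 34))
  for (res in others) {
    ab <- align_pair(seq_records("a", base), seq_records("b", res),
                     search_params(e_value_cutoff = Inf))
    ba <- align_pair(seq_records("b", res), seq_records("a", base),
                     search_params(e_value_cutoff = Inf))
    expect_equal(ab$percent_identity, ba$percent_identity)
  }
})

test_that("search_all filters, sorts and truncates per contract", {
  base <- random_protein(100, seed = 55)
  db <- seq_records(
    c("s3", "s1", "s2", "far", "q"),
    c(mutate_sequence(base, 70, seed = 1), mutate_sequence(base, 95, seed = 2),
      mutate_sequence(base, 85, seed = 3), random_protein(100, seed = 56),
      base))
  query <- seq_records("q", base)
  params <- search_params(e_value_cutoff = 1e-3)
  hits <- search_all(query, db, params)

  # brute-force sort oracle: independently sort the per-pair results
  all_pairs <- do.call(rbind, lapply(seq_len(nrow(db)), function(i) {
    align_pair(query, db[i, , drop = FALSE], params)
  }))
  all_pairs <- all_pairs[all_pairs$e_value <= 1e-3, ]
  expected <- all_pairs$subject_id[order(all_pairs$e_value,
                                         -all_pairs$bit_score,
                                         all_pairs$subject_id,
                                         method = "radix")]
  expect_equal(hits$subject_id, expected)
  expect_true("q" %in% hits$subject_id)  # the query's own record is a hit

  capped <- search_all(query, db, search_params(max_hits = 2))
  expect_equal(capped$subject_id, expected[1:2])

  none <- search_all(seq_records("w", "WPWPWPWP"), db[4, , drop = FALSE])
  expect_equal(nrow(none), 0)  # zero passing hits is an empty list
})

test_that("search_all is deterministic", {
  fx <- default_fixture()
  q <- fx$seqs[fx$seqs$protein_id == "F2_G1", ]
  h1 <- search_all(q, fx$seqs)
  h2 <- search_all(q, fx$seqs)
  expect_identical(h1, h2)
})

test_that("unknown substitution matrix and bad params are rejected", {
  expect_error(align_pair(seq_records("a", "MK"), seq_records("b", "MK"),
                          search_params(matrix_name = "NOSUCH62")),
               "unknown substitution matrix")
  expect_error(search_params(gap_open = 1, gap_extend = 5))
  expect_error(search_params(max_hits = 0))
})

test_that("external BLAST adapter errors usefully when absent, runs when present", {
  q <- seq_records("q", random_protein(120, seed = 77))
  expect_error(external_search(q, "dbpath", executable = "no-such-blast-exe"),
               "built-in backend")

  base <- q$residues
  db <- seq_records(c("near", "mid"),
                    c(mutate_sequence(base, 92, seed = 5),
                      mutate_sequence(base, 60, seed = 6)))
  dbdir <- tempfile(); dir.create(dbdir)
  fasta <- file.path(dbdir, "db.fasta")
  write_fasta(db, fasta)
  status <- system2("makeblastdb",
                    c("-in", fasta, "-dbtype", "prot"),
                    stdout = FALSE, stderr = FALSE)
  expect_equal(status, 0L)
  hits <- external_search(q, fasta, search_params(e_value_cutoff = 1e-3))
  expect_setequal(hits$subject_id, c("near", "mid"))
  expect_equal(hits$subject_id[1], "near")  # sorted best-first
  expect_true(all(diff(hits$e_value) >= 0))
})
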
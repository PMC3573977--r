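# toy two-genome system: query genome A, ortholog + confounders in genome B
toy_system <- function() {
  base <- random_protein(120, seed = 90)
  ortholog <- mutate_sequence(base, 88, seed = 1)
  seqs <- seq_records(
    c("qA", "othA", "oB", "pB", "oB2", "othB"),
    c(base, random_protein(120, seed = 91),
      ortholog,
      mutate_sequence(base, 95, seed = 2),   # closer within-genome paralog
      mutate_sequence(ortholog, 99, seed = 3),  # allele of oB
      random_protein(120, seed = 92)),
    taxon = c("A", "A", "B", "B", "B", "B"))
  gt <- seqs[, c("protein_id", "taxon")]
  list(seqs = seqs, genome_table = gt,
       query = seqs[seqs$protein_id == "qA", , drop = FALSE])
}

test_that("greedy preclustering handles identical and unrelated pairs", {
  same <- seq_records(c("first", "second"), rep(random_protein(50, 7), 2),
                      taxon = "t")
  cm <- precluster_genome(same)
  expect_equal(unname(cm[c("first", "second")]), c("first", "first"))

  far <- seq_records(c("x", "y"),
                     c(random_protein(50, 8), random_protein(50, 9)),
                     taxon = "t")
  cm2 <- precluster_genome(far)
  expect_equal(unname(cm2[c("x", "y")]), c("x", "y"))

  expect_error(precluster_genome(seq_records(c("a", "b"), c("MK", "ML"),
                                             taxon = c("t1", "t2"))),
               "single taxon")
})

test_that("preclustering matches the independent greedy oracle", {
  base <- random_protein(80, seed = 60)
  seqs <- seq_records(
    sprintf("g%d", 1:6),
    c(base, mutate_sequence(base, 99, seed = 1),
      mutate_sequence(base, 98, seed = 2),
      mutate_sequence(base, 70, seed = 3),
      substr(base, 1, 40),  # identical prefix: full coverage of the shorter
      random_protein(80, seed = 61)),
    taxon = "t")
  cm <- precluster_genome(seqs)
  oracle <- greedy_cluster_oracle(seqs)
  expect_equal(cm[sort(names(cm))], oracle[sort(names(oracle))])

  # every genome of the default fixture agrees with the oracle too
  fx <- default_fixture()
  for (tx in unique(fx$genome_table$taxon)) {
    genome <- fx$seqs[fx$seqs$taxon == tx, ]
    expect_lte(nrow(genome), 10)
    cm <- precluster_genome(genome)
    oracle <- greedy_cluster_oracle(genome)
    expect_equal(cm[sort(names(cm))], oracle[sort(names(oracle))],
                 info = tx)
  }
})

test_that("cluster members map to a representative that maps to itself", {
  fx <- default_fixture()
  g2 <- fx$seqs[fx$seqs$taxon == "G2", ]
  cm <- precluster_genome(g2)
  expect_equal(unname(cm[unname(cm)]), unname(cm))  # reps are fixed points
  expect_equal(unname(cm[["F1_G2_allele"]]), "F1_G2")  # allele absorbed
})

test_that("query taxon detection follows the 97%/90% rule in hit order", {
  gt <- data.frame(protein_id = c("h1", "h2", "h3"),
                   taxon = c("tax1", "tax2", "tax3"),
                   stringsAsFactors = FALSE)
  hits <- data.frame(
    query_id = "q", subject_id = c("h1", "h2", "h3"),
    percent_identity = c(98, 99, 97.5),
    query_coverage = c(95, 80, 95),
    e_value = c(1e-50, 1e-40, 1e-30), bit_score = c(200, 180, 160),
    aln_length = 100L, stringsAsFactors = FALSE)
  expect_equal(detect_query_taxon(hits, gt), "tax1")
  # h1 fails identity, h2 fails coverage -> h3 wins
  hits$percent_identity[1] <- 96.9
  expect_equal(detect_query_taxon(hits, gt), "tax3")
  hits$percent_identity[3] <- 90
  expect_equal(detect_query_taxon(hits, gt), "UNRESOLVED")
  # manual specification always wins
  expect_equal(detect_query_taxon(hits, gt, manual_taxon = "forced"),
               "forced")
})

test_that("mutual unique best hits give a (true, true) verdict", {
  sys <- toy_system()
  seqs <- sys$seqs[sys$seqs$protein_id != "pB", ]  # drop the confounder
  cms <- list(A = precluster_genome(seqs[seqs$taxon == "A", ]),
              B = precluster_genome(seqs[seqs$taxon == "B", ]))
  v <- reciprocal_best_hit(sys$query, "oB", "A", seqs,
                           seqs[, c("protein_id", "taxon")], cms)
  expect_equal(v, list(q2h = "true", h2q = "true"))
})

test_that("a closer paralog in the candidate genome breaks q2h", {
  sys <- toy_system()
  cms <- list(A = precluster_genome(sys$seqs[sys$seqs$taxon == "A", ]),
              B = precluster_genome(sys$seqs[sys$seqs$taxon == "B", ]))
  v_far <- reciprocal_best_hit(sys$query, "oB", "A", sys$seqs,
                               sys$genome_table, cms)
  expect_equal(v_far$q2h, "false")
  v_near <- reciprocal_best_hit(sys$query, "pB", "A", sys$seqs,
                                sys$genome_table, cms)
  expect_equal(v_near$q2h, "true")
})

test_that("an unresolved query genome yields h2q = na, not false", {
  sys <- toy_system()
  v <- reciprocal_best_hit(sys$query, "oB", "UNRESOLVED", sys$seqs,
                           sys$genome_table, list())
  expect_equal(v$h2q, "na")
  expect_true(v$q2h %in% c("true", "false"))  # q2h still assessed
})

test_that("verdicts are invariant under cluster-member substitution", {
  sys <- toy_system()
  seqs <- sys$seqs[sys$seqs$protein_id != "pB", ]
  gt <- seqs[, c("protein_id", "taxon")]
  cms <- list(A = precluster_genome(seqs[seqs$taxon == "A", ]),
              B = precluster_genome(seqs[seqs$taxon == "B", ]))
  expect_equal(unname(cms$B[["oB2"]]), "oB")  # allele clusters with oB
  v1 <- reciprocal_best_hit(sys$query, "oB", "A", seqs, gt, cms)
  v2 <- reciprocal_best_hit(sys$query, "oB2", "A", seqs, gt, cms)
  expect_equal(v1, v2)
  expect_equal(v1$q2h, "true")
})

test_that("a missing candidate sequence is an error", {
  sys <- toy_system()
  expect_error(reciprocal_best_hit(sys$query, "ghost", "A", sys$seqs,
                                   sys$genome_table, list()),
               "missing from collection")
})
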
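# independent brute-force scorer: explicit per-row lookup of the rating
# table, no arithmetic shared with the implementation
brute_score <- function(q2h, h2q, acc60, acc50, acc40, identity, is_ref) {
  pts <- 0
  for (d in c(q2h, h2q)) {
    pts <- pts + switch(d, true = 1, false = 0, na = 0.25)
  }
  if (acc60) pts <- pts + 0.5
  if (acc50) pts <- pts + 0.5
  if (acc40) pts <- pts + 0.5
  if (identity > 60) pts <- pts + 0.5
  if (identity > 50) pts <- pts + 0.5
  if (identity > 40) pts <- pts + 0.5
  if (is_ref) pts <- pts + 1
  pts
}

test_that("worked rating examples hit the scale's anchor points", {
  top <- score_reference(list(q2h = "true", h2q = "true"),
                         c(TRUE, TRUE, TRUE), 70, TRUE)
  expect_equal(top$total, 6.0)
  expect_equal(top$rb_points, 2)
  expect_equal(top$msc_points, 1.5)
  expect_equal(top$pairwise_points, 1.5)
  expect_equal(top$ref_point, 1)

  floor <- score_reference(list(q2h = "false", h2q = "false"),
                           c(FALSE, FALSE, FALSE), 35, TRUE)
  expect_equal(floor$total, 1.0)

  # both genomes unresolvable: the NA quarter-points keep the score above 1
  na_case <- score_reference(list(q2h = "na", h2q = "na"),
                             c(FALSE, FALSE, FALSE), 35, TRUE)
  expect_equal(na_case$total, 1.5)
})

test_that("pairwise identity bands are strict and cumulative", {
  at60 <- score_reference(list(q2h = "false", h2q = "false"),
                          c(FALSE, FALSE, FALSE), 60, FALSE)
  expect_equal(at60$pairwise_points, 1.0)  # exactly 60 earns only >50, >40
  at65 <- score_reference(list(q2h = "false", h2q = "false"),
                          c(FALSE, FALSE, FALSE), 65, FALSE)
  expect_equal(at65$pairwise_points, 1.5)  # 65 earns all three bands
  at40 <- score_reference(list(q2h = "false", h2q = "false"),
                          c(FALSE, FALSE, FALSE), 40, FALSE)
  expect_equal(at40$pairwise_points, 0)
})

test_that("scorer agrees with the brute-force oracle over all combinations", {
  verdicts <- c("true", "false", "na")
  grid <- expand.grid(q2h = verdicts, h2q = verdicts,
                      a60 = c(TRUE, FALSE), a50 = c(TRUE, FALSE),
                      a40 = c(TRUE, FALSE),
                      ident = c(35, 45, 55, 65),
                      ref = c(TRUE, FALSE),
                      stringsAsFactors = FALSE)
  totals <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    brk <- score_reference(list(q2h = g$q2h, h2q = g$h2q),
                           c(g$a60, g$a50, g$a40), g$ident, g$ref)
    expect_equal(brk$total, brute_score(g$q2h, g$h2q, g$a60, g$a50, g$a40,
                                        g$ident, g$ref))
    expect_equal(brk$total, brk$rb_points + brk$msc_points +
                   brk$pairwise_points + brk$ref_point)
    totals[i] <- brk$total
  }
  expect_equal(max(totals), 6)
  expect_equal(min(totals), 0)
  # feature maxima: 2 / 1.5 / 1.5 / 1
  expect_equal(max(vapply(verdicts, function(a) max(vapply(verdicts,
    function(b) score_reference(list(q2h = a, h2q = b),
                                c(FALSE, FALSE, FALSE), 0,
                                FALSE)$rb_points, numeric(1))),
    numeric(1))), 2)
})

test_that("improving any single feature never lowers the total", {
  base <- score_reference(list(q2h = "false", h2q = "false"),
                          c(FALSE, FALSE, TRUE), 45, TRUE)$total
  better <- list(
    score_reference(list(q2h = "true", h2q = "false"),
                    c(FALSE, FALSE, TRUE), 45, TRUE)$total,
    score_reference(list(q2h = "false", h2q = "false"),
                    c(FALSE, TRUE, TRUE), 45, TRUE)$total,
    score_reference(list(q2h = "false", h2q = "false"),
                    c(FALSE, FALSE, TRUE), 55, TRUE)$total)
  for (b in better) expect_gte(b, base)
})

test_that("ranking orders by score, then e-value, then subject id", {
  scored <- make_scored(c("pB", "pA", "pC", "pD"),
                        total = c(4, 6, 4, 4),
                        e_value = c(1e-10, 1e-50, 1e-50, 1e-50))
  ranked <- rank_results(scored)
  expect_equal(ranked$subject_id, c("pA", "pC", "pD", "pB"))
  expect_equal(ranked$rank, 1:4)
})

test_that("display filter drops scores strictly below the threshold", {
  ranked <- rank_results(make_scored(sprintf("p%d", 1:5),
                                     total = c(6, 4, 3, 2.5, 1)))
  kept <- apply_display_filter(ranked)
  expect_equal(kept$total, c(6, 4, 3))  # exactly 3 survives
  expect_equal(apply_display_filter(ranked, min_score = 0)$subject_id,
               ranked$subject_id)
  expect_equal(nrow(apply_display_filter(ranked[0, ])), 0)
})
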
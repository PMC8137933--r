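test_that("variance-penalized scores reproduce the reference table rows", {
  tab <- reference_force_table()
  expect_equal(nrow(tab), 10)
  computed <- vapply(seq_len(nrow(tab)), function(i) {
    mechanistic_score_from_stats(tab$mean[i], tab$sd[i], 5)$score
  }, 0)
  rounded <- cppforge:::round_half_away(computed, 1)
  # seven rows reproduce the printed score exactly at one decimal;
  # the remaining three differ by 0.1 (the printed inputs are rounded)
  exact <- c(628.0, 678.2, 680.1, 692.3, 721.2, 730.4, 746.6)
  expect_equal(rounded[1:7], exact)
  expect_true(all(abs(rounded - tab$printed_score) <= 0.1 + 1e-9))
})

test_that("scoring from stats and from replicas are consistent", {
  s <- mechanistic_score_from_stats(500, 0, 5)
  expect_equal(s$score, 500)
  expect_equal(mechanistic_score_from_stats(600, 10, 5, lambda = 0)$score, 600)

  r <- mechanistic_score_from_replicas(c(600, 610))
  expect_equal(r$m, 605)
  expect_equal(r$sd, stats::sd(c(600, 610)))
  expect_equal(r$score, 617.5, tolerance = 1e-12)

  expect_equal(mechanistic_score_from_replicas(rep(600, 5))$score, 600)

  set.seed(3)
  x <- rnorm(7, 650, 20)
  expect_equal(mechanistic_score_from_replicas(x)$score,
               mechanistic_score_from_stats(mean(x), stats::sd(x), 7)$score)

  expect_error(mechanistic_score_from_replicas(600), "2 replicas")
  expect_error(mechanistic_score_from_stats(600, -1, 5), "sd")
})

test_that("the score is monotone in sd, lambda and replica count", {
  base <- mechanistic_score_from_stats(600, 10, 5)$score
  expect_gt(mechanistic_score_from_stats(600, 20, 5)$score, base)
  expect_gt(mechanistic_score_from_stats(600, 10, 5, lambda = 5)$score, base)
  expect_lt(mechanistic_score_from_stats(600, 10, 20)$score, base)
  # score -> m as n grows
  expect_equal(mechanistic_score_from_stats(600, 10, 1e12)$score, 600,
               tolerance = 1e-5)
  # score >= m whenever lambda >= 0
  expect_gte(base, 600)
})

test_that("ranking sorts ascending with mean-then-id tie-breaks", {
  tab <- reference_force_table()
  rk <- rank_peptides(score_force_stats(tab))
  expect_equal(rk$peptide, tab$peptide)  # printed order is score-ascending
  expect_equal(rk$peptide[1], "YRGWHCRGITKNGIIFDIKW")
  expect_equal(rk$rank, 1:10)

  single <- rank_peptides(mechanistic_score_from_stats(1, 0, 5, peptide = "x"))
  expect_equal(single$rank, 1)

  # equal scores, unequal means: lower mean first
  a <- mechanistic_score_from_stats(600, 0, 5, peptide = "worse")
  b <- mechanistic_score_from_stats(590, 4 * sqrt(5), 5, peptide = "better")
  expect_equal(b$score, a$score)
  expect_equal(rank_peptides(list(a, b))$peptide, c("better", "worse"))
})

test_that("force tables are formatted at one decimal, half away from zero", {
  expect_equal(cppforge:::round_half_away(628.04999, 1), 628.0)
  expect_equal(cppforge:::fmt1(628.04999), "628.0")
  expect_equal(cppforge:::fmt1(628.05001), "628.1")
  expect_equal(cppforge:::fmt1(-1.25), "-1.3")

  tab <- reference_force_table()
  out <- report_table1(score_force_stats(tab))
  expect_equal(names(out), c("Rank", "Peptide", "Mean", "Standard deviation",
                             "Mechanistic score"))
  expect_equal(out$`Mechanistic score`[1], "628.0")
  expect_equal(out$Mean[1], "621.3")

  f <- withr::local_tempfile(fileext = ".tsv")
  report_table1(score_force_stats(tab), path = f)
  re <- utils::read.delim(f, check.names = FALSE)
  expect_equal(nrow(re), 10)
  expect_equal(re$Peptide[1], "YRGWHCRGITKNGIIFDIKW")
})

test_that("scores can be computed from trace files on disk", {
  proto <- smd_protocol(max_duration = 2, n_replicas = 2L, seed = 3L)
  pot <- membrane_potential(200)
  dir <- withr::local_tempdir()
  paths <- vapply(1:3, function(r) {
    tr <- run_steered(pot, proto, seed = 100 + r)
    p <- file.path(dir, sprintf("pep_rep%d.xvg", r))
    write_force_trace(tr, p)
    p
  }, "")
  sc <- score_force_files(list(pep = paths))
  expect_length(sc, 1)
  expect_equal(sc[[1]]$n, 3)
  direct <- vapply(1:3, function(r) {
    max_steering_force(run_steered(pot, proto, seed = 100 + r))
  }, 0)
  expect_equal(sc[[1]]$m, mean(direct), tolerance = 1e-8)
})
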
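# Generator, predictor and the candidate filters at desk scale. The GRU
# fits here use small hidden sizes and epoch caps so the whole file stays
# fast while still exercising real learning.

shared <- new.env()

shared_fixtures <- function() {
  if (is.null(shared$tr)) {
    shared$tr <- make_fixtures(fixture_spec(n_positives = 120L,
                                            n_negatives = 120L,
                                            length_range = c(8L, 18L),
                                            seed = 31L))
  }
  shared$tr
}

test_that("generator training reduces the loss and is deterministic", {
  tr <- shared_fixtures()
  cfg <- generator_config(hidden = 16L, epochs = 40L, seed = 2L)
  gen <- train_generator(tr$positives, cfg)
  expect_s3_class(gen, "cpp_generator")
  expect_lt(gen$best_loss, gen$loss_history[1])
  # checkpointed best loss is non-increasing by construction
  expect_equal(gen$best_loss, min(gen$loss_history))

  gen2 <- train_generator(tr$positives, cfg)
  g1 <- generate_sequences(gen, 5, 20, seed = 9)
  g2 <- generate_sequences(gen2, 5, 20, seed = 9)
  expect_identical(g1, g2)

  expect_error(train_generator(peptides(character(0))), "empty")
})

test_that("generated sequences have the requested length and alphabet", {
  tr <- shared_fixtures()
  gen <- train_generator(tr$positives,
                         generator_config(hidden = 16L, epochs = 25L,
                                          seed = 3L))
  g <- generate_sequences(gen, 10, 20, seed = 4)
  expect_length(g, 10)
  expect_true(all(nchar(g) == 20))
  letters_all <- unique(unlist(strsplit(unclass(g), "")))
  expect_true(all(letters_all %in% cppforge:::AA_STANDARD))
  pl <- attr(g, "prefix_lengths")
  expect_true(all(pl >= 1 & pl <= 20))

  g8 <- generate_sequences(gen, 3, 8, seed = 4)
  expect_true(all(nchar(g8) == 8))

  expect_error(generate_sequences(gen, 0), "count")
  expect_identical(generate_sequences(gen, 4, 20, seed = 7),
                   generate_sequences(gen, 4, 20, seed = 7))
})

test_that("a generator trained on a two-letter alphabet stays on it", {
  set.seed(5)
  seqs <- peptides(vapply(1:120, function(i) {
    paste(sample(c("A", "G"), sample(8:16, 1), TRUE), collapse = "")
  }, ""))
  gen <- train_generator(seqs, generator_config(hidden = 16L, epochs = 300L,
                                                lr = 0.02, patience = 60L,
                                                seed = 2L))
  g <- generate_sequences(gen, 100, 12, seed = 9,
                          prefix_alphabet = c("A", "G"))
  pl <- attr(g, "prefix_lengths")
  sampled <- unlist(lapply(seq_along(g), function(i) {
    ch <- strsplit(unclass(g)[[i]], "")[[1]]
    if (pl[i] < 12) ch[(pl[i] + 1):12] else character(0)
  }))
  expect_gt(length(sampled), 200)
  expect_gte(mean(sampled %in% c("A", "G")), 0.99)
})

test_that("predictor separates a planted compositional signal", {
  tr <- shared_fixtures()
  pred <- train_predictor(tr, predictor_config(hidden = 24L, epochs = 60L,
                                               seed = 6L))
  held <- make_fixtures(fixture_spec(n_positives = 80L, n_negatives = 80L,
                                     length_range = c(8L, 18L), seed = 77L))
  acc <- predictor_accuracy(pred, held$positives, held$negatives)
  expect_gt(acc, 0.8)

  # determinism
  pred2 <- train_predictor(tr, predictor_config(hidden = 24L, epochs = 60L,
                                                seed = 6L))
  expect_equal(score_likelihood(pred, held$positives[1:5])$likelihood,
               score_likelihood(pred2, held$positives[1:5])$likelihood)

  expect_error(train_predictor(training_set(peptides(character(0)),
                                            held$negatives)),
               "non-empty")
})

test_that("likelihood scores are squashed max-pooled partial scores", {
  # an untrained model already satisfies the structural contract
  tr <- shared_fixtures()
  pred <- train_predictor(tr, predictor_config(hidden = 8L, epochs = 1L,
                                               seed = 1L))
  x <- rand_peptides(12, c(1L, 15L), seed = 13)
  sc <- score_likelihood(pred, x)
  expect_true(all(sc$likelihood >= 0 & sc$likelihood <= 1))
  partials <- attr(sc, "partials")
  for (i in seq_along(x)) {
    expect_true(all(partials[[i]] >= 0 & partials[[i]] <= 1))
    expect_equal(sc$likelihood[i], max(partials[[i]]))
    expect_length(partials[[i]], nchar(unclass(x)[[i]]))
  }
  # a length-1 sequence's score is its single partial score
  one <- peptides(c(w = "W"))
  s1 <- score_likelihood(pred, one)
  expect_equal(s1$likelihood, attr(s1, "partials")[["w"]])

  # scoring in a batch equals scoring alone
  sub <- score_likelihood(pred, x[3])
  expect_equal(sub$likelihood, sc$likelihood[3])
})

test_that("top-k selection is score-descending with lexicographic ties", {
  sc <- structure(data.frame(id = c("a", "b", "c"),
                             sequence = c("WWW", "AAA", "CCC"),
                             likelihood = c(0.9, 0.5, 0.7)),
                  class = c("likelihood_scores", "data.frame"))
  expect_equal(select_top(sc, 2), c("a", "c"))
  expect_equal(select_top(sc, 3), c("a", "c", "b"))
  expect_warning(ids <- select_top(sc, 5), "exceeds")
  expect_length(ids, 3)
  expect_error(select_top(sc, 0), "k must be")

  tie <- structure(data.frame(id = c("z", "y", "x"),
                              sequence = c("GGC", "GGA", "GGG"),
                              likelihood = c(0.5, 0.5, 0.5)),
                   class = c("likelihood_scores", "data.frame"))
  expect_equal(select_top(tie, 3), c("y", "z", "x"))
})

test_that("redundancy removal clusters by alignment identity", {
  x <- peptides(c("AAAA", "AAAA"), ids = c("p", "q"))
  expect_equal(names(deduplicate_training(x, 0.35)), "p")

  x <- peptides(c("AAAA", "TTTT"), ids = c("p", "q"))
  expect_equal(names(deduplicate_training(x, 0.35)), c("p", "q"))

  x <- peptides(c("AAAA", "AAAT", "TTTT"), ids = c("a", "b", "c"))
  kept <- deduplicate_training(x, 0.5)
  expect_equal(unname(unclass(kept)), c("AAAA", "TTTT"))

  # order preserved, representatives first-seen
  expect_equal(names(kept), c("a", "c"))
  expect_error(deduplicate_training(x, 0), "cutoff")
})

test_that("synthesizability filtering keeps scores at or above threshold", {
  x <- rand_peptides(6, c(6L, 10L), seed = 2)
  expect_identical(filter_synthesizable(x, function(s) 5, 3), x)
  expect_length(filter_synthesizable(x, function(s) 0, 3), 0)

  mixed <- function(s) if (nchar(unclass(s)[[1]]) %% 2 == 0) 4 else 2
  kept <- filter_synthesizable(x, mixed, 3)
  expect_equal(unname(unclass(kept)),
               unname(unclass(x))[nchar(x) %% 2 == 0])

  expect_error(filter_synthesizable(x, function(s) stop("boom"), 3),
               names(x)[1])

  # bundled rule-based scorer: documented penalties
  expect_equal(default_synthesizability("GGGGGG"), 5)
  expect_equal(default_synthesizability("GWWWWWG"), 3)      # hydrophobic run
  expect_equal(default_synthesizability("GCGCGCG"), 3)      # 3 cysteines
  expect_equal(default_synthesizability(strrep("GA", 16)), 4)  # length > 30
})
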
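test_that("null ensembles preserve composition and are reproducible", {
  cfg <- null_config(n_shuffles = 25L, seed = 7L)
  ens <- generate_null_ensemble(pep_md(), cfg)
  expect_length(ens, 25)
  ref <- sort(strsplit("YRGWHCRGITKNGIIFDIKW", "")[[1]])
  for (s in unclass(ens)) {
    expect_equal(sort(strsplit(s, "")[[1]]), ref)
  }
  expect_identical(generate_null_ensemble(pep_md(), cfg), ens)

  expect_equal(unclass(generate_null_ensemble(peptides(c(x = "AA")),
                                              null_config(1L)))[[1]], "AA")
  expect_error(
    generate_null_ensemble(peptides(c(x = "AA")),
                           null_config(2L, unique = TRUE)),
    "distinct permutations")
  uq <- generate_null_ensemble(peptides(c(x = "ARNDC")),
                               null_config(30L, unique = TRUE, seed = 2L))
  expect_equal(anyDuplicated(unclass(uq)), 0)
})

test_that("force groups split by strict thresholds into a partition", {
  cfg <- null_config()
  sp <- split_force_groups(c(a = 750, b = 650, c = 700), cfg)
  expect_equal(sp$high, "a")
  expect_equal(sp$low, "b")
  expect_equal(sp$intermediate, "c")

  sp <- split_force_groups(c(x = 720, y = 680), cfg)
  expect_equal(sp$intermediate, c("x", "y"))

  sp <- split_force_groups(stats::setNames(numeric(0), character(0)), cfg)
  expect_equal(lengths(sp), c(high = 0, low = 0, intermediate = 0))

  forces <- stats::setNames(seq(600, 840, by = 12), paste0("p", 1:21))
  sp <- split_force_groups(forces, cfg)
  expect_equal(sort(c(sp$high, sp$low, sp$intermediate)),
               sort(names(forces)))
  expect_error(split_force_groups(c(a = Inf), cfg), "finite")
})

test_that("profile statistics follow the column definitions", {
  msa <- structure(matrix(rep("I", 30), nrow = 10), class = "peptide_msa")
  prof <- profile_stats(msa)
  expect_equal(prof$consensus, rep("I", 3))
  expect_equal(prof$consensus_fraction, rep(1, 3))
  expect_equal(prof$occupancy, rep(1, 3))
  expect_equal(prof$quality, rep(1, 3))

  col <- matrix(c(rep("I", 5), rep("-", 5)), ncol = 1)
  expect_equal(profile_stats(col)$occupancy, 0.5)

  col <- matrix(c("I", "I", "V", "L"), ncol = 1)
  prof <- profile_stats(col)
  expect_equal(prof$consensus, "I")
  expect_equal(prof$consensus_fraction, 0.5)
  # mean of the six pairwise BLOSUM62 scores, scaled over [-4, max self = 4]
  expect_equal(prof$quality, (mean(c(4, 3, 2, 3, 2, 1)) + 4) / 8)

  # consensus tie broken alphabetically
  col <- matrix(c("V", "I"), ncol = 1)
  expect_equal(profile_stats(col)$consensus, "I")

  prof <- profile_stats(star_msa(rand_peptides(5, c(5L, 9L), seed = 14)))
  expect_true(all(prof$consensus_fraction >= 0 & prof$consensus_fraction <= 1))
  expect_true(all(prof$occupancy >= 0 & prof$occupancy <= 1))
  expect_true(all(prof$quality >= 0 & prof$quality <= 1))
})

make_profile <- function(consensus, fraction, occupancy) {
  structure(data.frame(column = seq_along(consensus), consensus = consensus,
                       consensus_fraction = fraction, occupancy = occupancy,
                       quality = 1, stringsAsFactors = FALSE),
            class = c("alignment_profile", "data.frame"))
}

test_that("motif extraction finds planted runs and honours thresholds", {
  prof <- make_profile(c("G", "A", "I", "I", "W", "C", "G", "A"),
                       c(0.2, 0.3, 0.9, 0.9, 0.9, 0.2, 0.3, 0.2),
                       c(0.5, 0.5, 0.9, 0.9, 0.9, 0.5, 0.5, 0.5))
  m <- extract_motifs(prof, 0.5, 0.5, 2L)
  expect_equal(nrow(m), 1)
  expect_equal(m$pattern, "IIW")
  expect_equal(m$start, 3)
  expect_equal(m$length, 3)

  # thresholds at 1.0 on a noisy profile -> nothing
  expect_equal(nrow(extract_motifs(prof, 1, 1, 2L)), 0)

  # a single passing column is below min_len
  prof1 <- make_profile(c("G", "W", "G"), c(0.1, 0.9, 0.1), c(1, 1, 1))
  expect_equal(nrow(extract_motifs(prof1, 0.5, 0.5, 2L)), 0)

  # one interior sub-threshold column is bridged and rendered as '-'
  prof2 <- make_profile(c("W", "I", "C", "I", "G"),
                        c(0.9, 0.9, 0.1, 0.9, 0.9), rep(1, 5))
  m2 <- extract_motifs(prof2, 0.5, 0.5, 2L)
  expect_equal(m2$pattern, "WI-IG")

  expect_error(extract_motifs(prof, 0, 0.5), "thresholds")
})

test_that("charged-position comparison respects the window", {
  prof <- make_profile(rep("G", 20), rep(0.9, 20), rep(1, 20))
  prof$consensus[12] <- "K"
  seq <- peptides(c(p = "GGGGGGGGGGKGGGGGGGGG"))  # charged position 11
  r1 <- compare_charged_positions(seq, prof, window = 1)
  expect_true(r1$matched)
  expect_equal(r1$nearest_consensus_column, 12)
  r0 <- compare_charged_positions(seq, prof, window = 0)
  expect_false(r0$matched)
  expect_equal(attr(r0, "n_unmatched"), 1)

  # exact coincidence matches at window 0
  prof$consensus[11] <- "R"
  expect_true(all(compare_charged_positions(seq, prof, window = 0)$matched))

  expect_equal(nrow(compare_charged_positions(peptides(c(g = "GGGG")), prof)),
               0)
})

test_that("the reference peptide outranks its whole shuffle ensemble", {
  # end-to-end surrogate null: with the charged-position dispersion term in
  # the default mapping, the reference arrangement of charges is better
  # dispersed than any of the sampled composition-preserving permutations,
  # so its mechanistic score falls below the ensemble minimum
  na <- run_null_analysis(pep_md(), null_config(n_shuffles = 20L, seed = 42L))
  expect_lt(na$reference_score$score, min(na$shuffle_scores))
  expect_lt(na$forces[1], min(na$forces[-1]))
  # the split partitions the ensemble
  expect_equal(length(na$split$high) + length(na$split$low) +
                 length(na$split$intermediate), 20)

  # with the dispersion term disabled, shuffles share one potential
  flat_map <- potential_mapping(dispersion = 0)
  pots <- vapply(1:5, function(s) {
    sequence_to_potential(shuffle_sequence(pep_md(), s),
                          flat_map)$barrier_height
  }, 0)
  expect_equal(length(unique(pots)), 1)
})
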
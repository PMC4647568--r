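# Expected values below are the published per-species statistics; every one
# was re-derived by hand from the count distributions under the rule that
# half-score (transitional) specimens never enter the T_var numerator.
published_table1 <- data.frame(
  species = c("marmoratus", "pygmaeus", "ivanbureschi", "karelinii",
              "carnifex", "macedonicus", "cristatus", "dobrogicus"),
  n = c(58, 55, 175, 43, 66, 67, 122, 57),
  T_n = c(12, 12, 13, 13, 14, 14, 15, 17),
  T_var = c(13.8, 3.6, 10.3, 4.7, 12.1, 14.9, 14.8, 24.6),
  T_range = c(1, 1, 2, 1, 3, 2, 3, 3),
  S_tr = c(6.9, 1.8, 4.0, 2.3, 7.6, 9.0, 4.9, 1.8))

test_that("summarize_species reproduces every published species statistic", {
  rec <- table1_records()
  for (i in seq_len(nrow(published_table1))) {
    row <- published_table1[i, ]
    s <- summarize_species(rec, row$species, zone_filter = "central")
    expect_equal(s$n, row$n, info = row$species)
    expect_equal(s$T_n, row$T_n, info = row$species)
    expect_equal(round_half_up(s$T_var), row$T_var, info = row$species)
    expect_equal(s$T_range, row$T_range, info = row$species)
    expect_equal(round_half_up(s$S_tr), row$S_tr, info = row$species)
    # conservation: distribution counts sum to n, percentages in range
    expect_equal(sum(s$score_distribution), s$n)
    expect_true(s$T_var >= 0 && s$T_var <= 100)
    expect_true(s$S_tr >= 0 && s$S_tr <= 100)
  }
})

test_that("half-score specimens are excluded from the T_var numerator", {
  # a specimen contributes to at most one of T_var and S_tr: 14/57 non-modal
  # integers despite a half-score specimen in the sample
  s <- summarize_species(table1_records(), "dobrogicus")
  expect_equal(s$T_var, 100 * 14 / 57)
  expect_equal(s$S_tr, 100 * 1 / 57)
  # hybrid row: 24/68 non-modal integers, 5 half scores not among them
  h <- summarize_species(table3_records(), "cristatus_x_marmoratus")
  expect_equal(h$T_var, 100 * 24 / 68)
  expect_equal(h$S_tr, 100 * 5 / 68)
  expect_equal(h$T_n, 13)
})

test_that("degenerate sample gives all-zero variation statistics", {
  s <- summarize_species(make_records(7, counts = 13L), "testspecies")
  expect_equal(s$T_var, 0)
  expect_equal(s$S_tr, 0)
  expect_equal(s$T_range, 0)
  expect_equal(s$T_n, 13)
})

test_that("summaries are invariant to record order and respect zone filters", {
  rec <- table1_records()
  set.seed(11)
  shuffled <- rec[sample.int(nrow(rec)), ]
  s1 <- summarize_species(rec, "cristatus")
  s2 <- summarize_species(shuffled, "cristatus")
  s2$score_distribution <- s2$score_distribution[names(s1$score_distribution)]
  expect_equal(s1, s2)
  expect_error(summarize_species(rec, "cristatus", zone_filter = "fringe"),
               "no records")
  expect_error(summarize_species(rec, "unsampled_species"), "no records")
})

test_that("modal ties break toward the smaller count with a warning", {
  rec <- make_records(4, counts = c(12L, 12L, 14L, 14L))
  expect_warning(s <- summarize_species(rec, "testspecies"), "tie")
  expect_equal(s$T_n, 12)
})

test_that("expand_distribution round-trips through summarize_species", {
  set.seed(42)
  for (rep in 1:5) {
    scores <- sort(sample(seq(11, 18, by = 0.5), sample(3:6, 1)))
    counts <- sample(1:40, length(scores), replace = TRUE)
    # guarantee at least one integral score for the mode
    if (all(scores %% 1 != 0)) scores[1] <- floor(scores[1])
    dist <- data.frame(species = "rt", zone = "central",
                       score = scores, count = counts)
    rec <- expand_distribution(dist)
    s <- summarize_species(rec, "rt")
    got <- s$score_distribution[as.character(scores)]
    expect_equal(unname(got), as.numeric(counts))
    expect_equal(s$n, sum(counts))
  }
})

test_that("expand_distribution validates counts and annotation consistency", {
  expect_error(expand_distribution(
    data.frame(species = "a", score = 12, count = -1)), "nonnegative")
  tal <- data.frame(species = "a", n = 4, any_transformation = 3,
                    cervical_complete = 0, cervical_incomplete = 0,
                    sacral_left = 2, sacral_right = 1,
                    thoracic_to_sacral_incomplete = 0)
  expect_error(expand_distribution(
    data.frame(species = "a", score = c(12, 12.5), count = c(2, 2)),
    tally = tal), "inconsistent annotation totals")
})

test_that("transformation tallies reproduce the published per-species counts", {
  rec <- table2_records()
  t <- tally_transformations(rec, "marmoratus")
  expect_equal(t$any_transformation, 5)
  expect_equal(t$cervical_incomplete, 1)
  expect_equal(t$sacral_left, 1)
  expect_equal(t$sacral_right, 3)
  expect_equal(t$cervical_complete, 0)
  expect_equal(t$thoracic_to_sacral_incomplete, 0)
  # category sums equal the any-transformation count for every species
  tt <- tally_table(rec)
  expect_equal(tt$any_transformation,
               tt$cervical_complete + tt$cervical_incomplete +
                 tt$sacral_left + tt$sacral_right +
                 tt$thoracic_to_sacral_incomplete)
  expect_true(all(tt$any_transformation <= tt$n))
})

test_that("all-regular records tally to zero", {
  t <- tally_transformations(make_records(10), "testspecies")
  expect_equal(t$any_transformation, 0)
  expect_equal(t$sacral_left + t$sacral_right, 0)
})
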
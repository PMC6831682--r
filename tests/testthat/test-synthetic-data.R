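test_that("toy lexicons are reproducible and respect the word probability", {
  expect_identical(toy_lexicon(seed = 9), toy_lexicon(seed = 9))
  all_words <- toy_lexicon(word_probability = 1, seed = 1)
  expect_true(all(all_words$syllables$is_word))
  # word count within binomial 99% bounds
  lex <- toy_lexicon(word_probability = 0.7, seed = 2)
  n <- nrow(lex$syllables)
  expect_gte(length(lex$words), qbinom(0.005, n, 0.7))
  expect_lte(length(lex$words), qbinom(0.995, n, 0.7))
  # every generated syllable parses through the lexicon's own mapping
  parsed <- parse_pinyin(lex$syllables$pinyin, lex$mapping)
  expect_equal(parsed$T, lex$syllables$T)
})

test_that("degenerate or ambiguous inventories are rejected", {
  expect_error(toy_lexicon(onsets = "", glides = "", nuclei = "a",
                           codas = ""), "degenerate")
  expect_error(toy_lexicon(onsets = c("", "a")), "disjoint")
  expect_error(toy_lexicon(nuclei = c("", "a")), "nucleus")
})

test_that("trial generation is seed-deterministic", {
  lex <- toy_lexicon(seed = 1)
  s <- strategy_params()
  expect_identical(generate_trial(lex$words[5], s, lex, seed = 3),
                   generate_trial(lex$words[5], s, lex, seed = 3))
  expect_error(generate_trial("nope9", s, lex), "not in lexicon")
  expect_error(strategy_params(p_syllable = 1.2), "\\[0, 1\\]")
})

test_that("pure segment search yields an immediate-neighbour chain, RE = 1", {
  lex <- toy_lexicon(seed = 1)
  s <- strategy_params(p_syllable = 0, p_jump = 0,
                       error_nonword_rate = 0, error_repetition_rate = 0)
  for (seed in 1:5) {
    tr <- generate_trial(lex$words[10], s, lex, seed = seed)
    syl <- parse_pinyin(tr$response, lex$mapping)
    n <- nrow(syl)
    expect_true(all(edit_distance(syl[-n, ], syl[-1, ]) == 1L))
  }
})

test_that("pure syllable search produces tone-family runs with high SN", {
  lex <- toy_lexicon(seed = 1)
  s <- strategy_params(p_syllable = 1)
  sn <- vapply(1:20, function(seed) {
    tr <- generate_trial(lex$words[3], s, lex, seed = seed)
    syl <- parse_pinyin(tr$response, lex$mapping)
    n <- nrow(syl)
    mean(is_syllable_neighbor(syl[-n, ], syl[-1, ]))
  }, numeric(1))
  expect_gt(mean(sn > 0.5), 0.8)
})

test_that("mean SN increases with the syllable-move probability", {
  lex <- toy_lexicon(seed = 1)
  levels <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  mean_sn <- vapply(seq_along(levels), function(i) {
    s <- strategy_params(p_syllable = levels[i])
    mean(vapply(1:40, function(k) {
      tr <- generate_trial(lex$words[3], s, lex, seed = i * 1000 + k)
      syl <- parse_pinyin(tr$response, lex$mapping)
      n <- nrow(syl)
      mean(is_syllable_neighbor(syl[-n, ], syl[-1, ]))
    }, numeric(1)))
  }, numeric(1))
  expect_equal(cor(mean_sn, levels, method = "spearman"), 1)
})

test_that("cohorts are reproducible and carry ground truth", {
  c1 <- generate_cohort(n_participants = 6, seed = 11)
  c2 <- generate_cohort(n_participants = 6, seed = 11)
  expect_identical(c1$responses, c2$responses)
  expect_identical(c1$participants, c2$participants)
  expect_setequal(names(c1$participants),
                  c("participant_id", "english", "num_chinese",
                    "multilingual", "p_syllable", "p_jump",
                    "error_nonword_rate", "error_repetition_rate",
                    "mean_length"))
  expect_equal(length(c1$stimuli), 6)
  # stimuli come from distinct tone families
  atonal <- sub(".$", "", c1$stimuli)
  expect_equal(anyDuplicated(atonal), 0L)
})

test_that("zero effects and zero spread give identical parameters", {
  eff <- cohort_effects(english_on_p_syllable = 0,
                        numchinese_on_p_syllable = 0,
                        numchinese_on_p_jump = 0,
                        english_on_nonword = 0,
                        english_on_repetition = 0,
                        multilingual_on_error = 0,
                        participant_sd = 0, length_sd = 0)
  coh <- generate_cohort(n_participants = 8, effects = eff, seed = 3)
  expect_equal(length(unique(coh$participants$p_syllable)), 1L)
  expect_equal(length(unique(coh$participants$error_nonword_rate)), 1L)
})

test_that("covariate links push parameters in the configured directions", {
  coh <- generate_cohort(n_participants = 400, seed = 13)
  ppl <- coh$participants
  # higher English -> lower tone-family reliance and lower error rates
  expect_lt(cor(ppl$english, ppl$p_syllable), 0)
  expect_lt(cor(ppl$english, ppl$error_nonword_rate), 0)
  # more Chinese languages/dialects -> more jumps
  expect_gt(cor(ppl$num_chinese, ppl$p_jump), 0)
  # multilinguals have lower error rates on average
  expect_lt(mean(ppl$error_repetition_rate[ppl$multilingual == 1]),
            mean(ppl$error_repetition_rate[ppl$multilingual == 0]))
})

test_that("more jumps fragment the networks (NC rises with p_jump)", {
  lex <- toy_lexicon(seed = 1)
  mean_nc <- vapply(c(0.05, 0.45), function(pj) {
    s <- strategy_params(p_jump = pj)
    mean(vapply(1:30, function(k) {
      tr <- generate_trial(lex$words[3], s, lex, seed = 7000 + k)
      cls <- classify_productions(
        dplyr::mutate(tr, participant_id = "p", trial_id = "t",
                      stimulus = lex$words[3]), lex)
      ns <- network_scores(cls, lex$mapping)
      ifelse(is.na(ns$NC), 0, ns$NC)
    }, numeric(1)))
  }, numeric(1))
  expect_gt(mean_nc[2], mean_nc[1])
})

test_that("simulate_cohort writes the pipeline input format and sidecars", {
  d <- tempfile()
  coh <- simulate_cohort(d, config = list(n_participants = 4, seed = 5))
  expect_true(all(file.exists(file.path(
    d, c("responses.csv", "lexicon.csv", "mapping.tsv",
         "ground_truth.csv")))))
  back <- read_responses(file.path(d, "responses.csv"))
  expect_identical(nrow(back), nrow(coh$responses))
  # the written mapping reparses to the lexicon's mapping
  m2 <- pinyin_mapping(file.path(d, "mapping.tsv"))
  expect_equal(m2, coh$lexicon$mapping)
})
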
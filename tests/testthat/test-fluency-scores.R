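m <- pinyin_mapping()
lex_words <- c("wai4", "wai1", "shuai4", "shuan4", "xiang4", "xiang1",
               "shuai1", "zai4", "zai1", "zai3", "ma1", "ma3", "tu2", "du2",
               "wu2")

test_that("productions are classified correct / nonword / repetition", {
  cls <- classify_productions(
    trial_tbl(c("zai2", "ma1", "ma3", "ma1", "wu2"), "wai4"), lex_words)
  expect_equal(cls$response_type,
               c("nonword", "correct", "correct", "repetition", "correct"))
  expect_false(cls$is_word[1])       # zai2 marked nonword in the lexicon
  expect_false(cls$is_repetition[3]) # tone variant is not a repetition
  expect_true(cls$is_repetition[4])  # exact tonal repeat is
  # categories are exclusive and exhaustive
  expect_equal(sum(cls$response_type == "correct") +
                 sum(cls$response_type == "nonword") +
                 sum(cls$response_type == "repetition"), nrow(cls))
})

test_that("repetition flags follow the first-occurrence rule", {
  cls <- classify_productions(trial_tbl(c("ma1", "ma3", "ma1"), "wai4"),
                              lex_words)
  expect_equal(cls$is_repetition, c(FALSE, FALSE, TRUE))
  # a repeated nonword counts as repetition, keeping counts additive
  cls2 <- classify_productions(trial_tbl(c("zai2", "zai2"), "wai4"),
                               lex_words)
  expect_equal(cls2$response_type, c("nonword", "repetition"))
})

test_that("WE sums printed weights over correct productions only", {
  # three correct responses at edits (1, 1, 2) from wai4: 1 + 1 + 0.75
  cls <- classify_productions(
    trial_tbl(c("wai1", "shuai4", "shuan4", "zai2"), "wai4"), lex_words)
  sc <- score_trials(cls, m)
  expect_equal(sc$WE, 2.75)
  expect_equal(sc$n_correct, 3L)
  # no correct responses -> WE 0
  sc0 <- score_trials(
    classify_productions(trial_tbl(c("zai2", "ba9x") , "wai4",
                                   trial = "t9")[1, ], lex_words), m)
  expect_equal(sc0$WE, 0)
})

test_that("RE is the mean successive weight over ALL productions", {
  # every consecutive pair an immediate neighbour -> RE = 1
  cls <- classify_productions(
    trial_tbl(c("shuai4", "shuai1", "shuan1", "shuan4"), "wai4"), lex_words)
  expect_equal(score_trials(cls, m)$RE, 1)
  # pair weights alternating 1, 0.5, 1, 0.5 -> mean 0.75
  cls2 <- classify_productions(
    trial_tbl(c("wai4", "shuai4", "xiang4", "xiang1", "shuai1"), "ma1"),
    lex_words)
  expect_equal(score_trials(cls2, m)$RE, 0.75)
  # all successive pairs sharing no similarity -> RE = 0
  cls3 <- classify_productions(trial_tbl(c("wai4", "tu2", "wai4"), "ma1"),
                               lex_words)
  expect_equal(score_trials(cls3, m)$RE, 0)
  # errors are included: the repetition pair ma1-ma1 has weight 1
  cls4 <- classify_productions(trial_tbl(c("ma1", "ma1"), "wai4"), lex_words)
  expect_equal(score_trials(cls4, m)$RE, 1)
})

test_that("SN is the proportion of successive syllable-neighbour pairs", {
  sn <- function(x) score_trials(
    classify_productions(trial_tbl(x, "wai4"), lex_words), m)$SN
  expect_equal(sn(c("zai4", "zai1", "zai2", "zai3")), 1)
  expect_equal(sn(c("wai4", "zai4", "zai1")), 0.5)
  expect_equal(sn(c("wai4", "tu2", "ma1")), 0)
  expect_equal(sn(c("ma1", "ma1")), 1)  # repetitions included
})

test_that("Error sums nonwords and repetitions", {
  cls <- classify_productions(
    trial_tbl(c("zai2", "ba1x", "ma1", "ma1", "wu2"), "wai4")[-2, ],
    lex_words)
  sc <- score_trials(cls, m)
  expect_equal(sc$Error, sc$n_nonword + sc$n_repetition)
  all_ok <- score_trials(
    classify_productions(trial_tbl(c("ma1", "wu2"), "wai4"), lex_words), m)
  expect_equal(all_ok$Error, 0L)
})

test_that("single-production trials report RE and SN as missing", {
  sc <- score_trials(
    classify_productions(trial_tbl("ma1", "wai4"), lex_words), m)
  expect_true(is.na(sc$RE) && is.na(sc$SN))
  expect_equal(sc$WE, edit_weight(parse_pinyin("wai4", m),
                                  parse_pinyin("ma1", m)))
})

test_that("WE is order-invariant on repetition-free trials; RE is not", {
  resp <- c("shuai4", "xiang4", "zai4", "ma1", "wu2")
  sc1 <- score_trials(classify_productions(trial_tbl(resp, "wai4"),
                                           lex_words), m)
  sc2 <- score_trials(classify_productions(trial_tbl(rev(resp), "wai4"),
                                           lex_words), m)
  expect_equal(sc1$WE, sc2$WE)
  expect_equal(sc1$n_correct, sc2$n_correct)
  # WE never exceeds the correct count
  expect_lte(sc1$WE, sc1$n_correct)
})

test_that("unparseable productions are reported with trial context", {
  cls <- classify_productions(trial_tbl(c("ma1", "blorp3"), "wai4",
                                        participant = "p7", trial = "t2"),
                              lex_words)
  expect_error(score_trials(cls, m), "blorp3")
  expect_error(score_trials(cls, m), "p7/t2")
})
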
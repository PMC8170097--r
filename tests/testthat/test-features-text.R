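# task-specific, semantic and syntactic feature extractors

en_lex <- load_lexicon(language = "en")

test_that("per-IU features count the worked example correctly", {
  tr <- worked_example_transcript()
  m <- match_mentions(tr, en_lex)
  f <- per_iu_features(m, en_lex)
  expect_length(f, 48)
  expect_equal(f[["boy_count"]], 3)       # boy, boy, brother
  expect_equal(f[["boy_ratio"]], 0.6)
  expect_equal(f[["boy_mentioned"]], 1)
  expect_equal(f[["girl_count"]], 1)      # sister
  expect_equal(f[["cookie_count"]], 1)
  expect_equal(f[["window_mentioned"]], 0)
  expect_equal(sum(f[paste0(en_lex$ius$name, "_ratio")]), 1)
})

test_that("per-IU features degrade gracefully with no mentions", {
  empty <- match_mentions(transcript_from_tokens(list("nothing")), en_lex)
  f <- per_iu_features(empty, en_lex)
  expect_true(all(f == 0))
  one <- match_mentions(transcript_from_tokens(list(c("the", "jar"))), en_lex)
  f1 <- per_iu_features(one, en_lex)
  expect_equal(f1[["jar_ratio"]], 1)
})

test_that("half switches count adjacent side changes", {
  # boy(L) stool(L) sink(R) girl(L): switches L->R->L = 2
  tr <- transcript_from_tokens(list(c("boy", "stool", "sink", "girl")))
  m <- match_mentions(tr, en_lex)
  f <- spatial_features(m, en_lex, "halves", word_count(tr))
  expect_equal(f[["half_switches"]], 2)
  expect_equal(f[["left_word_count"]], 3)
  expect_equal(f[["right_word_count"]], 1)
})

test_that("spatial features are zero with no mentions and saturate at full coverage", {
  none <- match_mentions(transcript_from_tokens(list("nothing")), en_lex)
  for (div in c("halves", "quadrants", "stripes"))
    expect_true(all(spatial_features(none, en_lex, div, 1) == 0))

  # one utterance per IU so "cookie" and "jar" cannot fuse into the
  # multi-word keyword "cookie jar"
  all16 <- transcript_from_tokens(as.list(en_lex$ius$name))
  m <- match_mentions(all16, en_lex)
  for (div in c("halves", "quadrants", "stripes")) {
    f <- spatial_features(m, en_lex, div, word_count(all16))
    expect_true(all(f[grep("percent_uttered", names(f))] == 1))
  }
})

test_that("the semantic summary reproduces every worked-example cell", {
  tr <- worked_example_transcript()
  m <- match_mentions(tr, en_lex)
  f <- iu_summary_features(m, word_count(tr), 15, en_lex)
  expect_equal(f[["num_unique_IU"]], 3)
  expect_equal(f[["num_unique_keywords"]], 4)
  expect_equal(f[["num_total_keywords"]], 5)
  expect_equal(round(f[["unique_IU_density"]], 4), 0.1667)
  expect_equal(round(f[["total_IU_density"]], 4), 0.2778)
  expect_equal(round(f[["keyword_to_non_keyword_ratio"]], 4), 0.3846)
  expect_equal(f[["percentage_of_keywords_mentioned"]], 0.1875)
  expect_equal(f[["keyword_TTR"]], 0.8)
  expect_equal(round(f[["total_IU_efficiency"]], 2), 0.33)
  expect_equal(f[["unique_IU_efficiency"]], 0.2)
  expect_equal(round(f[["unique_keyword_density"]], 2), 0.22)
})

test_that("semantic summary edge cases behave as specified", {
  none <- match_mentions(transcript_from_tokens(list("nothing")), en_lex)
  f <- iu_summary_features(none, 10, NA, en_lex)
  expect_equal(unname(f[c("num_unique_IU", "num_total_keywords",
                          "unique_IU_density", "total_IU_density",
                          "keyword_to_non_keyword_ratio")]),
               c(0, 0, 0, 0, 0))
  expect_true(is.na(f[["keyword_TTR"]]))
  expect_true(is.na(f[["total_IU_efficiency"]]))

  # all words are keywords -> ratio undefined, with a warning
  all_kw <- match_mentions(transcript_from_tokens(list(c("boy", "girl"))),
                           en_lex)
  expect_warning(f2 <- iu_summary_features(all_kw, 2, 10, en_lex),
                 "undefined")
  expect_true(is.na(f2[["keyword_to_non_keyword_ratio"]]))
  expect_equal(f2[["keyword_TTR"]], 1)
})

test_that("keyword/non-keyword ratio equals the density identity", {
  set.seed(7)
  vocab <- c("boy", "girl", "cookie", "water", "the", "is", "a", "nice")
  for (i in 1:15) {
    toks <- sample(vocab, sample(5:20, 1), replace = TRUE)
    tr <- transcript_from_tokens(list(toks))
    m <- match_mentions(tr, en_lex)
    wc <- word_count(tr)
    if (wc == nrow(m)) next
    f <- iu_summary_features(m, wc, 10, en_lex)
    d <- f[["total_IU_density"]]
    expect_equal(f[["keyword_to_non_keyword_ratio"]], d / (1 - d))
  }
})

test_that("lexical statistics aggregate frequency and length", {
  freq <- c(a = 0.02, cat = 0.001)
  tr <- transcript_from_tokens(list(c("a", "cat")))
  m <- match_mentions(tr, en_lex)   # no keywords here
  f <- lexical_stats(tr, m, freq)
  expect_equal(f[["mean_word_frequency_all"]], 0.0105)
  expect_equal(f[["max_word_frequency_all"]], 0.02)
  expect_equal(f[["mean_word_length_all"]], 2)
  expect_true(is.na(f[["mean_word_frequency_keywords"]]))

  tr2 <- transcript_from_tokens(list(c("dog", "mouse")))  # lengths 3, 5
  f2 <- lexical_stats(tr2, m, freq)
  expect_equal(f2[["mean_word_length_all"]], 4)
  expect_equal(f2[["max_word_length_all"]], 5)
  # out-of-vocabulary words look up as zero frequency
  expect_equal(f2[["mean_word_frequency_all"]], 0)
})

test_that("TTR and MATTR agree with hand counts", {
  expect_equal(ttr(transcript_from_tokens(list(rep("word", 10)))), 0.1)
  expect_equal(ttr(transcript_from_tokens(list(letters[1:7]))), 1)
  expect_equal(ttr(worked_example_transcript()), 11 / 18)

  expect_equal(mattr(transcript_from_tokens(list(rep("word", 10)))), 0.1)
  expect_equal(mattr(transcript_from_tokens(list(letters[1:12]))), 1)
  # a b a b ... a (11 tokens): both windows hold 2 types
  ab <- transcript_from_tokens(list(rep(c("a", "b"), length.out = 11)))
  expect_equal(mattr(ab), 0.2)
  expect_true(is.na(mattr(transcript_from_tokens(list(character(0))))))
})

test_that("MATTR with window = word count equals TTR", {
  set.seed(11)
  for (i in 1:10) {
    toks <- sample(letters[1:6], sample(3:25, 1), replace = TRUE)
    tr <- transcript_from_tokens(list(toks))
    expect_equal(mattr(tr, window = word_count(tr)), ttr(tr))
  }
})

test_that("sentence statistics match the worked example", {
  f <- sentence_stats(worked_example_transcript())
  expect_equal(f[["number_of_sentences"]], 4)
  expect_equal(f[["word_count"]], 18)
  expect_equal(f[["mean_words_per_sentence"]], 4.5)
  expect_equal(sentence_stats(
    transcript_from_tokens(list("one")))[["mean_words_per_sentence"]], 1)
  expect_true(all(is.na(sentence_stats(structure(list(utterances = list()),
                                       class = "speech_transcript")))))
})

test_that("POS statistics compute counts, ratios and class ratios", {
  tg <- data.frame(upos = c("DET", "NOUN", "AUX", "VERB"))
  f <- pos_stats(tg)
  expect_equal(f[["NOUN_count"]], 1)
  expect_equal(f[["NOUN_ratio"]], 0.25)
  expect_equal(f[["open_closed_ratio"]], 1)   # NOUN+VERB vs DET+AUX
  # counts over word tags sum to the word count
  expect_equal(sum(f[paste0(setdiff(c("ADJ","ADP","ADV","AUX","CCONJ","DET",
                                      "INTJ","NOUN","NUM","PART","PRON",
                                      "PROPN","SCONJ","SYM","VERB","X"),
                                    "PUNCT"), "_count")]), 4)

  f2 <- pos_stats(data.frame(upos = c("PRON", "PRON")))
  expect_true(is.na(f2[["pronoun_noun_ratio"]]))

  f3 <- pos_stats(data.frame(upos = "PUNCT"))
  expect_equal(f3[["PUNCT_count"]], 1)
  expect_equal(f3[["PUNCT_ratio"]], 1)
  expect_true(is.na(f3[["NOUN_ratio"]]))

  expect_error(pos_stats(data.frame(upos = "NOUNS")), "NOUNS")
})

test_that("dependency lengths aggregate over non-root arcs", {
  two <- data.frame(upos = c("NOUN", "VERB"), head_offset = c(1, 0))
  f <- dependency_stats(two)
  expect_equal(unname(f), c(1, 1, 1))

  chain <- data.frame(upos = c("X", "X", "X"), head_offset = c(0, -1, -1))
  expect_equal(dependency_stats(chain)[["dependency_length_mean"]], 1)

  root_only <- data.frame(upos = "NOUN", head_offset = 0)
  expect_true(all(is.na(dependency_stats(root_only))))
})

test_that("the builtin tagger is deterministic and covers both languages", {
  tr <- worked_example_transcript()
  tg <- tag_transcript(tr, "en")
  expect_identical(tg, tag_transcript(tr, "en"))
  expect_true(all(tg$upos %in% c("ADJ","ADP","ADV","AUX","CCONJ","DET","INTJ",
                                 "NOUN","NUM","PART","PRON","PROPN","PUNCT",
                                 "SCONJ","SYM","VERB","X")))
  expect_equal(tg$upos[tolower(tg$surface) == "boy"][1], "NOUN")
  expect_equal(tg$upos[tolower(tg$surface) == "is"][1], "AUX")
  expect_equal(tg$upos[tolower(tg$surface) == "stealing"][1], "VERB")

  trf <- transcript_from_tokens(list(c("le", "garçon", "tombe", ".")))
  tgf <- tag_transcript(trf, "fr")
  expect_equal(tgf$upos, c("DET", "NOUN", "VERB", "PUNCT"))
  # deterministic head scheme: root is the verb
  expect_equal(tgf$head_offset[3], 0)
})

test_that("whole-record extraction covers the registry with finite values", {
  f <- extract_text_features(worked_example_transcript(), en_lex,
                             duration_s = 15)
  reg <- feature_registry(c("task", "semantic", "syntactic"))
  expect_identical(names(f), reg$feature)
  expect_equal(length(f), 89 + 25 + 44)
  expect_false(any(is.na(f)))

  # semantic features are invariant to punctuation tokens
  no_punct <- transcript_from_tokens(lapply(
    worked_example_transcript()$utterances,
    function(u) u$surface[u$is_word]))
  f2 <- extract_text_features(no_punct, en_lex, duration_s = 15)
  sem <- feature_registry("semantic")$feature
  expect_equal(f[sem], f2[sem])
})

test_that("the full registry has unique names and documented family sizes", {
  reg <- feature_registry()
  expect_equal(anyDuplicated(reg$feature), 0)
  expect_equal(unname(table(reg$subgroup)[c("task", "semantic", "syntactic",
                                            "paralinguistic")]),
               c(89, 25, 44, 209), ignore_attr = TRUE)
})
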
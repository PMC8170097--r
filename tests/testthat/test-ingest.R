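# CHAT parsing, word counting, lexicon loading and mention matching

test_that("a minimal well-formed tier parses into words plus punctuation", {
  tr <- parse_chat("*PAR:\tthere is a boy .")
  expect_length(tr$utterances, 1)
  expect_equal(sum(tr$utterances[[1]]$is_word), 4)
  expect_equal(sum(!tr$utterances[[1]]$is_word), 1)
  expect_equal(word_count(tr), 4)
})

test_that("only the requested speaker tier is returned, in order", {
  doc <- paste0("@Begin\n",
                "*INV:\twhat do you see ?\n",
                "*PAR:\tthere is a boy .\n",
                "%mor:\tpro|there v|is det|a n|boy .\n",
                "*INV:\tanything else ?\n",
                "*PAR:\tthe sink overflows .\n")
  tr <- parse_chat(doc)
  expect_length(tr$utterances, 2)
  expect_equal(tolower(tr$utterances[[1]]$surface[4]), "boy")
  expect_equal(tolower(tr$utterances[[2]]$surface[2]), "sink")
})

test_that("a document without the speaker raises an empty-transcript error", {
  expect_error(parse_chat("*INV:\twhat do you see ?"), "no utterances")
})

test_that("a malformed tier line raises a parse error naming the line", {
  expect_error(parse_chat(c("*PAR:\tfine .", "*PA R bad line")),
               "malformed tier line 2")
})

test_that("CHAT markup is stripped but repeated words are kept", {
  tr <- parse_chat("*PAR:\tthe boy [//] the girl falls .")
  expect_equal(transcript_words(tr), c("the", "boy", "the", "girl", "falls"))

  tr2 <- parse_chat(
    "*PAR:\t<the boy> [/] the boy &=laughs is (.) falling &-uh (be)cause .")
  expect_equal(transcript_words(tr2),
               c("the", "boy", "the", "boy", "is", "falling", "because"))

  tr3 <- parse_chat("*PAR:\tthe woman xxx is washing +...")
  expect_equal(transcript_words(tr3), c("the", "woman", "is", "washing"))
})

test_that("continuation lines are joined to their tier", {
  tr <- parse_chat("*PAR:\tthe boy is\n\tstealing a cookie .")
  expect_equal(word_count(tr), 6)
})

test_that("word_count matches the worked example and ignores punctuation", {
  expect_equal(word_count(worked_example_transcript()), 18)
  expect_equal(word_count(transcript_from_tokens(list(character(0)))), 0)
  expect_equal(word_count(transcript_from_tokens(list(c("a", "b", "c", ".")))), 3)
})

test_that("default lexicons validate and carry the 16 IUs with synonyms", {
  for (lg in c("en", "fr")) {
    lex <- load_lexicon(language = lg)
    expect_equal(nrow(lex$ius), 16)
    expect_true(all(lengths(lex$keywords) >= 1))
  }
  en <- load_lexicon(language = "en")
  expect_true(all(c("boy", "brother", "son") %in% en$keywords$boy))
})

test_that("lexicon validation reports missing IUs and bad region labels", {
  en <- jsonlite::fromJSON(system.file("extdata", "lexicon_en.json",
                                       package = "speechmarkers"),
                           simplifyVector = FALSE)
  broken <- en
  broken$ius <- Filter(function(e) e$name != "curtain", broken$ius)
  f <- tempfile(fileext = ".json")
  jsonlite::write_json(broken, f, auto_unbox = TRUE)
  expect_error(load_lexicon(f, "en"), "curtain")

  broken2 <- en
  broken2$ius[[1]]$quadrant <- "north"
  jsonlite::write_json(broken2, f, auto_unbox = TRUE)
  expect_error(load_lexicon(f, "en"), "north")

  broken3 <- en
  broken3$ius[[2]]$keywords <- list()
  jsonlite::write_json(broken3, f, auto_unbox = TRUE)
  expect_error(load_lexicon(f, "en"), "empty keyword set")
})

test_that("mentions match case-insensitively and via synonyms", {
  lex <- load_lexicon(language = "en")
  tr <- transcript_from_tokens(list(c("The", "Boy", "is", "a", "brother", ".")))
  m <- match_mentions(tr, lex)
  expect_equal(nrow(m), 2)
  expect_equal(unique(m$iu), "boy")

  none <- match_mentions(transcript_from_tokens(list(c("nothing", "here"))),
                         lex)
  expect_equal(nrow(none), 0)
})

test_that("longest match wins and spans never overlap", {
  lex <- load_lexicon(language = "en")
  tr <- transcript_from_tokens(list(c("the", "cookie", "jar", "fell", ".")))
  m <- match_mentions(tr, lex)
  expect_equal(m$iu, "jar")
  expect_equal(m$keyword, "cookie jar")

  # bare "cookie" still maps to the cookie IU
  m2 <- match_mentions(transcript_from_tokens(list(c("a", "cookie", "."))), lex)
  expect_equal(m2$iu, "cookie")
})

test_that("plural inflections match and map to the base keyword", {
  lex <- load_lexicon(language = "en")
  m <- match_mentions(transcript_from_tokens(list(c("two", "cookies", "and",
                                                    "dishes", "."))), lex)
  expect_equal(m$keyword, c("cookie", "dish"))
  frlex <- load_lexicon(language = "fr")
  mf <- match_mentions(transcript_from_tokens(list(c("les", "rideaux", "."))),
                       frlex)
  expect_equal(mf$iu, "curtain")
})

test_that("mention positions are strictly increasing and bounded by words", {
  lex <- load_lexicon(language = "en")
  set.seed(42)
  vocab <- c("boy", "girl", "cookie", "jar", "the", "is", "falling", "uh",
             "water", "sink", "dish", "towel")
  for (i in 1:20) {
    toks <- sample(vocab, sample(3:15, 1), replace = TRUE)
    tr <- transcript_from_tokens(list(toks, sample(vocab, 4, replace = TRUE)))
    m <- match_mentions(tr, lex)
    if (nrow(m) > 1) expect_true(all(diff(m$position) > 0))
    expect_lte(nrow(m), word_count(tr))
    # per-IU count equals the sum of its keywords' match counts
    for (iu in unique(m$iu))
      expect_equal(sum(m$iu == iu),
                   sum(table(m$keyword[m$iu == iu])))
  }
})

test_that("matching is deterministic", {
  lex <- load_lexicon(language = "en")
  tr <- worked_example_transcript()
  expect_identical(match_mentions(tr, lex), match_mentions(tr, lex))
})
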
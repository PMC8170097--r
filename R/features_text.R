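#' Text feature families
#'
#' Three families are computed from the transcript: task-specific features
#' (per-IU counts and spatial coverage of the picture), semantic features
#' (global information-unit summaries, word frequency/length, lexical
#' diversity) and syntactic features (sentence statistics, POS tag
#' distributions, dependency lengths).  Every feature has a registered name
#' and belongs to exactly one subgroup; `feature_registry()` enumerates the
#' full registry.
#'
#' @name features_text
NULL

region_key <- function(x) gsub("-", "_", x)

#' Per-information-unit task features
#'
#' For each of the 16 IUs emits `{iu}_mentioned` (0/1), `{iu}_count` and
#' `{iu}_ratio` (count over all mentions; 0 when nothing was mentioned).
#'
#' @param mentions a `mention_sequence` from [match_mentions()].
#' @param lexicon the `iu_lexicon` used for matching.
#' @return named numeric vector of 48 task-specific features.
#' @export
per_iu_features <- function(mentions, lexicon) {
  ius <- lexicon$ius$name
  counts <- vapply(ius, function(u) sum(mentions$iu == u), numeric(1))
  total <- sum(counts)
  ratios <- if (total > 0) counts / total else rep(0, length(ius))
  vals <- c(rbind(as.numeric(counts > 0), counts, ratios))
  names(vals) <- c(rbind(paste0(ius, "_mentioned"),
                         paste0(ius, "_count"),
                         paste0(ius, "_ratio")))
  vals
}

#' Spatial task features over a picture division
#'
#' The picture is divided into halves, quadrants or vertical stripes; each
#' IU belongs to one region per scheme.  Per region the features are
#' `{region}_word_count` (keyword tokens mapped there),
#' `{region}_ttr` (unique keywords / keyword tokens, 0 if none),
#' `{region}_keyword_to_word_ratio` (keyword tokens / transcript word
#' count) and `{region}_percent_uttered` (unique IUs mentioned / IUs
#' assigned).  For halves, `half_switches` counts changes of side along
#' the mention sequence.
#'
#' @inheritParams per_iu_features
#' @param division `"halves"`, `"quadrants"` or `"stripes"`.
#' @param word_count transcript word count (denominator of the
#'   keyword-to-word ratio).
#' @return named numeric vector.
#' @export
spatial_features <- function(mentions, lexicon,
                             division = c("halves", "quadrants", "stripes"),
                             word_count) {
  division <- match.arg(division)
  col <- c(halves = "half", quadrants = "quadrant", stripes = "stripe")[division]
  regions <- switch(division, halves = .HALVES, quadrants = .QUADRANTS,
                    stripes = .STRIPES)
  iu_region <- stats::setNames(lexicon$ius[[col]], lexicon$ius$name)
  m_region <- iu_region[mentions$iu]

  vals <- numeric(0)
  for (rg in regions) {
    sel <- !is.na(m_region) & m_region == rg
    n_tok <- sum(sel)
    n_unique_kw <- length(unique(mentions$keyword[sel]))
    n_unique_iu <- length(unique(mentions$iu[sel]))
    n_assigned <- sum(iu_region == rg)
    v <- c(n_tok,
           if (n_tok > 0) n_unique_kw / n_tok else 0,
           if (word_count > 0) n_tok / word_count else 0,
           if (n_assigned > 0) n_unique_iu / n_assigned else 0)
    names(v) <- paste0(region_key(rg),
                       c("_word_count", "_ttr", "_keyword_to_word_ratio",
                         "_percent_uttered"))
    vals <- c(vals, v)
  }
  if (division == "halves") {
    sw <- if (length(m_region) >= 2)
      sum(m_region[-1] != m_region[-length(m_region)]) else 0
    vals <- c(vals, half_switches = as.numeric(sw))
  }
  vals
}

#' Global information-unit summary features
#'
#' The semantic summary of the mention sequence: counts of unique IUs,
#' unique keywords and total keyword tokens; densities relative to the word
#' count; the keyword-to-non-keyword ratio; the fraction of the 16 IUs
#' covered; the keyword type-token ratio; and per-second IU efficiencies
#' when the response duration is known.
#'
#' @inheritParams per_iu_features
#' @param word_count transcript word count (> 0).
#' @param duration_s response duration in seconds; `NA` leaves the two
#'   efficiency features missing.
#' @return named numeric vector of 11 semantic features.
#' @export
iu_summary_features <- function(mentions, word_count, duration_s = NA,
                                lexicon) {
  stopifnot(word_count > 0)
  n_iu_total <- nrow(lexicon$ius)
  n_unique_iu <- length(unique(mentions$iu))
  n_unique_kw <- length(unique(mentions$keyword))
  n_total_kw <- nrow(mentions)

  if (word_count == n_total_kw) {
    warning("word count equals total keyword count; ",
            "keyword_to_non_keyword_ratio is undefined")
    k2nk <- NA_real_
  } else {
    k2nk <- n_total_kw / (word_count - n_total_kw)
  }

  c(num_unique_IU = n_unique_iu,
    num_unique_keywords = n_unique_kw,
    num_total_keywords = n_total_kw,
    unique_IU_density = n_unique_iu / word_count,
    total_IU_density = n_total_kw / word_count,
    keyword_to_non_keyword_ratio = k2nk,
    unique_keyword_density = n_unique_kw / word_count,
    percentage_of_keywords_mentioned = n_unique_iu / n_iu_total,
    keyword_TTR = if (n_total_kw > 0) n_unique_kw / n_total_kw else NA_real_,
    total_IU_efficiency = if (is.na(duration_s)) NA_real_
                          else n_total_kw / duration_s,
    unique_IU_efficiency = if (is.na(duration_s)) NA_real_
                           else n_unique_iu / duration_s)
}

#' Load a packaged word-frequency table
#'
#' Relative word frequencies (share of tokens in a large reference corpus,
#' values in `[0, 1]`) for the core vocabulary of picture descriptions.
#' Out-of-vocabulary words look up as 0.
#'
#' @param language `"en"` or `"fr"`.
#' @param path optional path to a custom two-column CSV (`word,frequency`).
#' @return named numeric vector, names lowercased.
#' @export
load_wordfreq <- function(language = c("en", "fr"), path = NULL) {
  language <- match.arg(language)
  if (is.null(path))
    path <- system.file("extdata", paste0("wordfreq_", language, ".csv"),
                        package = "speechmarkers", mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8")
  stats::setNames(as.numeric(tab$frequency), tolower(tab$word))
}

lookup_freq <- function(words, freq) {
  v <- unname(freq[tolower(words)])
  v[is.na(v)] <- 0
  v
}

#' Word frequency and word length statistics
#'
#' Mean, median and max of word frequency and of word length, over all
#' word tokens and over mentioned keywords (12 features).  Keyword
#' statistics use the matched canonical keyword of each mention instance;
#' with no mentions they are missing.
#'
#' @param transcript a `speech_transcript`.
#' @param mentions a `mention_sequence`.
#' @param freq named numeric frequency lookup, as from [load_wordfreq()].
#' @return named numeric vector of 12 semantic features.
#' @export
lexical_stats <- function(transcript, mentions, freq) {
  words <- transcript_words(transcript)
  stat3 <- function(x) if (length(x) == 0)
    c(NA_real_, NA_real_, NA_real_) else
    c(mean(x), stats::median(x), max(x))
  wf <- stat3(lookup_freq(words, freq))
  wl <- stat3(nchar(words))
  kw <- mentions$keyword
  kf <- stat3(lookup_freq(kw, freq))
  kl <- stat3(nchar(gsub(" ", "", kw)))
  stats::setNames(
    c(wf, kf, wl, kl),
    c(paste0(c("mean", "median", "max"), "_word_frequency_all"),
      paste0(c("mean", "median", "max"), "_word_frequency_keywords"),
      paste0(c("mean", "median", "max"), "_word_length_all"),
      paste0(c("mean", "median", "max"), "_word_length_keywords")))
}

#' Type-token ratio
#'
#' Unique lowercased word tokens divided by the word count.
#'
#' @param transcript a `speech_transcript`.
#' @return ratio in `(0, 1]`, or `NA` for an empty transcript.
#' @export
ttr <- function(transcript) {
  w <- transcript_words(transcript)
  if (length(w) == 0) return(NA_real_)
  length(unique(w)) / length(w)
}

#' Moving-average type-token ratio
#'
#' The TTR is computed in every sliding window of `window` consecutive word
#' tokens (words 1..w, then 2..w+1, ...) and the window TTRs are averaged,
#' reducing the dependence of lexical diversity on response length.  A
#' transcript shorter than the window falls back to the whole-text TTR.
#'
#' @param transcript a `speech_transcript`.
#' @param window window size in word tokens (default 10).
#' @return ratio, or `NA` for an empty transcript.
#' @export
mattr <- function(transcript, window = 10) {
  stopifnot(window >= 1)
  w <- transcript_words(transcript)
  n <- length(w)
  if (n == 0) return(NA_real_)
  if (n < window) return(ttr(transcript))
  tt <- vapply(seq_len(n - window + 1L), function(i)
    length(unique(w[i:(i + window - 1L)])) / window, numeric(1))
  mean(tt)
}

#' Sentence-level statistics
#'
#' @param transcript a `speech_transcript`.
#' @return named numeric: `number_of_sentences` (utterance count),
#'   `mean_words_per_sentence`, `word_count`; all `NA` with zero
#'   utterances.
#' @export
sentence_stats <- function(transcript) {
  ns <- length(transcript$utterances)
  if (ns == 0)
    return(c(number_of_sentences = NA_real_,
             mean_words_per_sentence = NA_real_, word_count = NA_real_))
  wc <- word_count(transcript)
  c(number_of_sentences = ns, mean_words_per_sentence = wc / ns,
    word_count = wc)
}

.OPEN_CLASS  <- c("ADJ", "ADV", "INTJ", "NOUN", "PROPN", "VERB")
.CLOSED_CLASS <- c("ADP", "AUX", "CCONJ", "DET", "NUM", "PART", "PRON")

#' Part-of-speech tag statistics
#'
#' Counts and ratios per universal POS tag, plus noun/verb, pronoun/noun,
#' determiner/noun and open/closed class ratios.  Ratio denominators are
#' the word count (punctuation excluded); `PUNCT_ratio` alone is relative
#' to all tokens.  Ratios with a zero denominator are missing.
#'
#' @param tagged data frame of tagged tokens with a `upos` column (see
#'   [tag_transcript()]).
#' @return named numeric vector of 38 syntactic features.
#' @export
pos_stats <- function(tagged) {
  upos <- tagged$upos
  bad <- setdiff(unique(upos), .UPOS)
  if (length(bad))
    stop("unknown POS tag(s): ", paste(bad, collapse = ", "), call. = FALSE)
  counts <- vapply(.UPOS, function(tg) sum(upos == tg), numeric(1))
  n_all <- length(upos)
  n_words <- n_all - counts[["PUNCT"]]
  ratios <- if (n_words > 0) counts / n_words else rep(NA_real_, length(.UPOS))
  names(ratios) <- .UPOS
  if (n_all > 0) ratios[["PUNCT"]] <- counts[["PUNCT"]] / n_all

  safe_div <- function(a, b) if (!is.na(b) && b > 0) a / b else NA_real_
  open <- sum(counts[.OPEN_CLASS]); closed <- sum(counts[.CLOSED_CLASS])
  out <- c(counts, ratios,
           noun_verb_ratio = safe_div(counts[["NOUN"]], counts[["VERB"]]),
           pronoun_noun_ratio = safe_div(counts[["PRON"]], counts[["NOUN"]]),
           determiner_noun_ratio = safe_div(counts[["DET"]], counts[["NOUN"]]),
           open_closed_ratio = safe_div(open, closed))
  names(out)[seq_along(.UPOS)] <- paste0(.UPOS, "_count")
  names(out)[length(.UPOS) + seq_along(.UPOS)] <- paste0(.UPOS, "_ratio")
  out
}

#' Dependency length statistics
#'
#' The dependency length of a non-root token is the absolute signed
#' distance to its head; mean, median and max are aggregated over all
#' non-root tokens of the transcript (roots contribute no arc).
#'
#' @param tagged data frame with `head_offset` (and optionally `utterance`)
#'   columns.
#' @return named numeric: `dependency_length_mean`, `_median`, `_max`; all
#'   `NA` (with a warning) when no arcs exist.
#' @export
dependency_stats <- function(tagged) {
  if (is.null(tagged$head_offset) || all(is.na(tagged$head_offset))) {
    warning("no dependency parse available; dependency features missing")
    len <- numeric(0)
  } else {
    len <- abs(tagged$head_offset[!is.na(tagged$head_offset) &
                                  tagged$head_offset != 0])
  }
  if (length(len) == 0)
    return(c(dependency_length_mean = NA_real_,
             dependency_length_median = NA_real_,
             dependency_length_max = NA_real_))
  c(dependency_length_mean = mean(len),
    dependency_length_median = stats::median(len),
    dependency_length_max = max(len))
}

## --- registry and whole-record extraction ---------------------------------

task_feature_names <- function() {
  c(c(rbind(paste0(.IU_NAMES, "_mentioned"), paste0(.IU_NAMES, "_count"),
            paste0(.IU_NAMES, "_ratio"))),
    as.vector(outer(region_key(.HALVES),
                    c("_word_count", "_ttr", "_keyword_to_word_ratio",
                      "_percent_uttered"), paste0)),
    "half_switches",
    as.vector(outer(region_key(.QUADRANTS),
                    c("_word_count", "_ttr", "_keyword_to_word_ratio",
                      "_percent_uttered"), paste0)),
    as.vector(outer(region_key(.STRIPES),
                    c("_word_count", "_ttr", "_keyword_to_word_ratio",
                      "_percent_uttered"), paste0)))
}

semantic_feature_names <- function() {
  c("num_unique_IU", "num_unique_keywords", "num_total_keywords",
    "unique_IU_density", "total_IU_density", "keyword_to_non_keyword_ratio",
    "unique_keyword_density", "percentage_of_keywords_mentioned",
    "keyword_TTR", "total_IU_efficiency", "unique_IU_efficiency",
    paste0(c("mean", "median", "max"), "_word_frequency_all"),
    paste0(c("mean", "median", "max"), "_word_frequency_keywords"),
    paste0(c("mean", "median", "max"), "_word_length_all"),
    paste0(c("mean", "median", "max"), "_word_length_keywords"),
    "TTR", "MATTR")
}

syntactic_feature_names <- function() {
  c("number_of_sentences", "mean_words_per_sentence", "word_count",
    "dependency_length_mean", "dependency_length_median",
    "dependency_length_max",
    paste0(.UPOS, "_count"), paste0(.UPOS, "_ratio"),
    "noun_verb_ratio", "pronoun_noun_ratio", "determiner_noun_ratio",
    "open_closed_ratio")
}

#' Feature registry
#'
#' Every feature the pipeline can compute, with its subgroup.  The
#' implemented family sizes are reported by the registry itself (they are
#' not forced to match any external tally): 89 task-specific, 25 semantic,
#' 44 syntactic, 209 paralinguistic.
#'
#' @param subgroups which subgroups to include.
#' @return data frame with columns `feature` and `subgroup`.
#' @export
feature_registry <- function(subgroups = c("task", "semantic", "syntactic",
                                           "paralinguistic")) {
  blocks <- list(
    task = task_feature_names(),
    semantic = semantic_feature_names(),
    syntactic = syntactic_feature_names(),
    paralinguistic = paralinguistic_feature_names())
  blocks <- blocks[subgroups]
  out <- data.frame(
    feature = unlist(blocks, use.names = FALSE),
    subgroup = rep(names(blocks), lengths(blocks)),
    stringsAsFactors = FALSE)
  stopifnot(!anyDuplicated(out$feature))
  out
}

#' Extract all text features from one record
#'
#' Runs the task-specific, semantic and syntactic extractors on a
#' transcript and returns one named vector covering every registered text
#' feature.
#'
#' @param transcript a `speech_transcript`.
#' @param lexicon an `iu_lexicon` for the transcript's language.
#' @param duration_s response duration in seconds (`NA` allowed; the two
#'   efficiency features are then missing).
#' @param freq word-frequency lookup; defaults to the packaged table for
#'   the lexicon's language.
#' @param tagger tagging backend, a function `(transcript, language,
#'   lexicon) -> tagged tokens`; defaults to the builtin deterministic
#'   tagger.
#' @return named numeric vector over the task, semantic and syntactic
#'   registries.
#' @export
extract_text_features <- function(transcript, lexicon, duration_s = NA,
                                  freq = NULL, tagger = tag_transcript) {
  if (is.null(freq)) freq <- load_wordfreq(lexicon$language)
  mentions <- match_mentions(transcript, lexicon)
  wc <- word_count(transcript)
  tagged <- tagger(transcript, lexicon$language, lexicon)

  vals <- c(per_iu_features(mentions, lexicon),
            spatial_features(mentions, lexicon, "halves", wc),
            spatial_features(mentions, lexicon, "quadrants", wc),
            spatial_features(mentions, lexicon, "stripes", wc),
            if (wc > 0) iu_summary_features(mentions, wc, duration_s, lexicon)
            else stats::setNames(rep(NA_real_, 11),
                                 semantic_feature_names()[1:11]),
            lexical_stats(transcript, mentions, freq),
            TTR = ttr(transcript), MATTR = mattr(transcript),
            sentence_stats(transcript),
            dependency_stats(tagged),
            pos_stats(tagged))

  reg <- c(task_feature_names(), semantic_feature_names(),
           syntactic_feature_names())
  out <- vals[reg]
  names(out) <- reg
  out
}
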
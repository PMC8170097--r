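#' Transcript objects
#'
#' A `speech_transcript` holds one participant's response as an ordered list
#' of utterances; each utterance is a data frame with columns `surface`
#' (the token as transcribed) and `is_word` (`FALSE` exactly for punctuation
#' tokens).  Word order is never rearranged by any operation in the package.
#'
#' @param utterances list of character vectors, one per utterance.  Tokens
#'   equal to `.`, `?`, `!` or `,` are flagged as punctuation.
#' @return an object of class `speech_transcript`.
#' @export
transcript_from_tokens <- function(utterances) {
  punct <- c(".", "?", "!", ",")
  utts <- lapply(utterances, function(toks) {
    toks <- as.character(toks)
    data.frame(surface = toks, is_word = !(toks %in% punct),
               stringsAsFactors = FALSE)
  })
  structure(list(utterances = utts), class = "speech_transcript")
}

#' @export
print.speech_transcript <- function(x, ...) {
  cat(sprintf("<speech_transcript: %d utterances, %d words>\n",
              length(x$utterances), word_count(x)))
  invisible(x)
}

#' Word tokens of a transcript
#'
#' @param transcript a `speech_transcript`.
#' @param lower lowercase the surfaces?
#' @return character vector of word tokens (punctuation excluded), in order.
#' @export
transcript_words <- function(transcript, lower = TRUE) {
  w <- unlist(lapply(transcript$utterances,
                     function(u) u$surface[u$is_word]), use.names = FALSE)
  if (is.null(w)) w <- character(0)
  if (lower) tolower(w) else w
}

#' Count word tokens in a transcript
#'
#' Counts tokens flagged as words across all utterances; punctuation tokens
#' are excluded.
#'
#' @param transcript a `speech_transcript`.
#' @return integer word count.
#' @export
word_count <- function(transcript) {
  sum(vapply(transcript$utterances, function(u) sum(u$is_word), integer(1)))
}

## --- CHAT parsing ----------------------------------------------------------

# Normalization applied to a CHAT main-tier string before tokenization.
# Removals are deterministic: timing bullets, event codes (&=, &-, &+ ...),
# all bracketed annotation groups ([//], [/], [=! ...], [?], ...), angle
# brackets around retraced groups (the words themselves are kept), pause
# marks "(.)", "(..)"; shortenings "(be)cause" are expanded to "because";
# unintelligible/untranscribed placeholders xxx/yyy/www are dropped.
clean_chat_utterance <- function(s) {
  # timing bullets: \x15 12345_67890 \x15 or unicode bullet-delimited
  s <- gsub("\x15[^\x15]*\x15", " ", s)
  s <- gsub("\u2022[^\u2022]*\u2022", " ", s)
  # bracketed annotation groups, including retracing/repetition markers
  s <- gsub("\\[[^]]*\\]", " ", s)
  # angle brackets delimit the retraced words: keep the words
  s <- gsub("[<>]", " ", s)
  # events and fragments: &=laughs &-uh &+fr &~ ...
  s <- gsub("&[=+~-]?\\S*", " ", s)
  # pause marks
  s <- gsub("\\(\\.+\\)", " ", s)
  # shortenings: (be)cause -> because ; drops the parentheses only
  s <- gsub("[()]", "", s)
  # special-form markers: word@o, word@u ...
  s <- gsub("@\\S*", "", s)
  # clause-linking / trailing-off codes: +... +//. +"/. etc.
  s <- gsub("\\+\\S*", " ", s)
  s
}

tokenize_chat <- function(s) {
  # split off sentence punctuation as separate tokens
  s <- gsub("([.?!,])", " \\1 ", s)
  toks <- strsplit(trimws(s), "\\s+")[[1]]
  toks <- toks[nzchar(toks)]
  toks[!(tolower(toks) %in% c("xxx", "yyy", "www"))]
}

#' Parse a CHAT document into a transcript
#'
#' Reads a CHAT (.cha) document and returns the utterances of one speaker
#' tier, in order, with transcription markup stripped.  Timing bullets,
#' event codes and retracing/repetition markers are removed (the repeated
#' words themselves are kept) and shortenings such as `(be)cause` are
#' expanded.  Word tokens and sentence punctuation are retained, the latter
#' flagged with `is_word = FALSE`.
#'
#' @param text the CHAT document as a single string, or a character vector of
#'   lines.
#' @param speaker tier code of the speaker to extract (default `"PAR"`, the
#'   participant).
#' @return a `speech_transcript`.
#' @export
parse_chat <- function(text, speaker = "PAR") {
  lines <- if (length(text) == 1L && grepl("\n", text))
    strsplit(text, "\n", fixed = TRUE)[[1]] else as.character(text)

  utterances <- list()
  current <- NULL      # text of the tier currently being read
  active <- FALSE      # is `current` the requested speaker's tier?

  flush <- function() {
    if (active && !is.null(current)) {
      toks <- tokenize_chat(clean_chat_utterance(current))
      if (length(toks))
        utterances[[length(utterances) + 1L]] <<- toks
    }
    current <<- NULL
    active <<- FALSE
  }

  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (startsWith(ln, "*")) {
      m <- regmatches(ln, regexec("^\\*([A-Za-z0-9]+):[ \t]*(.*)$", ln))[[1]]
      if (length(m) == 0L)
        stop(sprintf("malformed tier line %d: %s", i, ln), call. = FALSE)
      flush()
      current <- m[3]
      active <- identical(toupper(m[2]), toupper(speaker))
    } else if (startsWith(ln, "\t") || startsWith(ln, "    ")) {
      # continuation of the previous tier
      if (!is.null(current)) current <- paste(current, trimws(ln))
    } else {
      # @ headers, %dependent tiers, blank lines: end any open tier
      flush()
    }
  }
  flush()

  if (length(utterances) == 0L)
    stop(sprintf("no utterances found for speaker '*%s'", speaker),
         call. = FALSE)
  transcript_from_tokens(utterances)
}

#' Read a CHAT file
#'
#' @param path path to a `.cha` file.
#' @inheritParams parse_chat
#' @return a `speech_transcript`.
#' @export
read_chat <- function(path, speaker = "PAR") {
  parse_chat(readLines(path, warn = FALSE, encoding = "UTF-8"),
             speaker = speaker)
}
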
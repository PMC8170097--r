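#' Information-unit lexicons
#'
#' The Cookie Theft picture is scored against 16 information units (IUs):
#' boy, girl, woman, kitchen, exterior, cookie, jar, stool, sink, plate,
#' dishcloth, water, window, cupboard, dish, curtain.  Each IU maps to a set
#' of synonymous keywords (the boy may be called "brother" or "son") and to
#' one region under each of three spatial divisions of the picture: halves
#' (left/right), quadrants (NE/NW/SE/SW) and vertical stripes (most-left,
#' center-left, center-right, most-right).
#'
#' @name iu_lexicon
NULL

.IU_NAMES <- c("boy", "girl", "woman", "kitchen", "exterior", "cookie",
               "jar", "stool", "sink", "plate", "dishcloth", "water",
               "window", "cupboard", "dish", "curtain")
.HALVES    <- c("left", "right")
.QUADRANTS <- c("NE", "NW", "SE", "SW")
.STRIPES   <- c("most-left", "center-left", "center-right", "most-right")

# Small rule-based inflector used to expand keyword surface forms so that
# plural mentions ("cookies", "rideaux") match without a lemmatizer.  For a
# multi-word keyword only the last word is inflected.
inflect_forms <- function(keyword, language) {
  parts <- strsplit(keyword, " ", fixed = TRUE)[[1]]
  last <- parts[length(parts)]
  extra <- character(0)
  if (language == "en") {
    extra <- if (grepl("(s|x|z|ch|sh)$", last)) paste0(last, "es")
             else paste0(last, "s")
  } else if (language == "fr") {
    extra <- if (grepl("(eau|eu)$", last)) paste0(last, "x")
             else if (!grepl("(s|x|z)$", last)) paste0(last, "s")
             else character(0)
  }
  vapply(extra, function(e)
    paste(c(parts[-length(parts)], e), collapse = " "), character(1),
    USE.NAMES = FALSE)
}

#' Load an information-unit lexicon
#'
#' Reads a lexicon configuration (JSON with keys `language` and `ius`, each
#' IU entry carrying `name`, `keywords`, `half`, `quadrant`, `stripe`) and
#' validates it: all 16 IUs must be present, each with a non-empty keyword
#' set and a known label for each region scheme.  Keywords are lowercased
#' and deduplicated, and a surface-form table including rule-based plural
#' inflections is precomputed for matching.
#'
#' @param path path to a lexicon JSON file, or `NULL` to load the packaged
#'   default for `language`.
#' @param language `"en"` or `"fr"`.
#' @return an object of class `iu_lexicon`.
#' @export
load_lexicon <- function(path = NULL, language = c("en", "fr")) {
  language <- match.arg(language)
  if (is.null(path)) {
    path <- system.file("extdata", paste0("lexicon_", language, ".json"),
                        package = "speechmarkers", mustWork = TRUE)
  }
  cfg <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!is.null(cfg$language)) language <- cfg$language

  problems <- character(0)
  entries <- list()
  for (e in cfg$ius) {
    nm <- e$name
    kws <- unique(tolower(trimws(unlist(e$keywords))))
    kws <- kws[nzchar(kws)]
    if (length(kws) == 0L)
      problems <- c(problems, sprintf("'%s': empty keyword set", nm))
    if (!(e$half %in% .HALVES))
      problems <- c(problems, sprintf("'%s': unknown half '%s'", nm, e$half))
    if (!(e$quadrant %in% .QUADRANTS))
      problems <- c(problems,
                    sprintf("'%s': unknown quadrant '%s'", nm, e$quadrant))
    if (!(e$stripe %in% .STRIPES))
      problems <- c(problems,
                    sprintf("'%s': unknown stripe '%s'", nm, e$stripe))
    entries[[nm]] <- list(name = nm, keywords = kws, half = e$half,
                          quadrant = e$quadrant, stripe = e$stripe)
  }
  missing <- setdiff(.IU_NAMES, names(entries))
  if (length(missing))
    problems <- c(problems,
                  sprintf("missing IU entries: %s",
                          paste(missing, collapse = ", ")))
  extra <- setdiff(names(entries), .IU_NAMES)
  if (length(extra))
    problems <- c(problems,
                  sprintf("unknown IU entries: %s",
                          paste(extra, collapse = ", ")))
  if (length(problems))
    stop("invalid IU lexicon:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  entries <- entries[.IU_NAMES]

  # surface-form table: form -> canonical keyword -> IU
  forms <- do.call(rbind, lapply(entries, function(e) {
    do.call(rbind, lapply(e$keywords, function(kw) {
      fs <- unique(c(kw, inflect_forms(kw, language)))
      data.frame(form = fs, keyword = kw, iu = e$name,
                 nwords = lengths(strsplit(fs, " ", fixed = TRUE)),
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(forms) <- NULL
  # a form that inflection makes collide with another keyword keeps its
  # first (base-form) owner; base forms are inserted first per IU
  forms <- forms[!duplicated(forms$form), ]

  structure(list(
    language = language,
    ius = data.frame(
      name = .IU_NAMES,
      half = vapply(entries, `[[`, character(1), "half"),
      quadrant = vapply(entries, `[[`, character(1), "quadrant"),
      stripe = vapply(entries, `[[`, character(1), "stripe"),
      row.names = NULL, stringsAsFactors = FALSE),
    keywords = lapply(entries, `[[`, "keywords"),
    forms = forms), class = "iu_lexicon")
}

#' @export
print.iu_lexicon <- function(x, ...) {
  cat(sprintf("<iu_lexicon [%s]: %d IUs, %d surface forms>\n",
              x$language, nrow(x$ius), nrow(x$forms)))
  invisible(x)
}

#' Match information-unit mentions in a transcript
#'
#' Scans the word-token stream (case-insensitively) for lexicon surface
#' forms.  Multi-word keywords are matched longest-first and never overlap,
#' so "cookie jar" yields one mention of the jar IU, not an extra cookie
#' mention.  Matching does not cross utterance boundaries.
#'
#' @param transcript a `speech_transcript`.
#' @param lexicon an `iu_lexicon`.
#' @return a data frame (class `mention_sequence`) with one row per mention:
#'   `position` (index into the word-token stream, strictly increasing),
#'   `keyword` (canonical keyword) and `iu`.
#' @export
match_mentions <- function(transcript, lexicon) {
  forms <- lexicon$forms
  max_n <- max(forms$nwords)
  lut <- split(seq_len(nrow(forms)), forms$form)
  # only attempt multi-word windows where the first word can start one
  multi_first <- unique(vapply(strsplit(forms$form[forms$nwords > 1], " ",
                                        fixed = TRUE),
                               `[[`, character(1), 1L))

  res_pos <- integer(0); res_kw <- character(0); res_iu <- character(0)
  offset <- 0L
  for (u in transcript$utterances) {
    w <- tolower(u$surface[u$is_word])
    n <- length(w)
    i <- 1L
    while (i <= n) {
      hit <- NULL
      kmax <- if (w[i] %in% multi_first) min(max_n, n - i + 1L) else 1L
      for (k in rev(seq_len(kmax))) {                    # longest first
        cand <- if (k == 1L) w[i]
                else paste(w[i:(i + k - 1L)], collapse = " ")
        j <- lut[[cand]]
        if (!is.null(j)) { hit <- forms[j[1L], ]; break }
      }
      if (!is.null(hit)) {
        res_pos <- c(res_pos, offset + i)
        res_kw <- c(res_kw, hit$keyword)
        res_iu <- c(res_iu, hit$iu)
        i <- i + hit$nwords
      } else i <- i + 1L
    }
    offset <- offset + n
  }
  structure(data.frame(position = res_pos, keyword = res_kw, iu = res_iu,
                       stringsAsFactors = FALSE),
            class = c("mention_sequence", "data.frame"))
}
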
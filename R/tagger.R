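#' Deterministic part-of-speech tagging backend
#'
#' Tagging and dependency annotation sit behind a small backend contract:
#' tokens in, tagged tokens (surface, universal POS tag, signed offset to
#' the syntactic head) out.  The packaged `"builtin"` backend is a
#' deterministic lexicon-and-suffix tagger covering the closed classes of
#' English and French plus the vocabulary of Cookie Theft descriptions; it
#' requires no model download and gives bit-identical output across runs.
#' A pretrained tagger can be plugged in by passing a function with the
#' same signature wherever a `tagger` argument is accepted.
#'
#' Tags are drawn from the 17-tag universal set: ADJ, ADP, ADV, AUX, CCONJ,
#' DET, INTJ, NOUN, NUM, PART, PRON, PROPN, PUNCT, SCONJ, SYM, VERB, X.
#'
#' @name tagging
NULL

.UPOS <- c("ADJ", "ADP", "ADV", "AUX", "CCONJ", "DET", "INTJ", "NOUN",
           "NUM", "PART", "PRON", "PROPN", "PUNCT", "SCONJ", "SYM",
           "VERB", "X")

.TAG_LEXICON <- list(
  en = list(
    DET  = c("the", "a", "an", "this", "that", "these", "those", "some",
             "any", "no", "each", "every", "his", "her", "its", "their",
             "my", "your", "our"),
    PRON = c("he", "she", "it", "they", "i", "you", "we", "him", "them",
             "me", "us", "who", "something", "everything", "one",
             "himself", "herself"),
    ADP  = c("in", "on", "of", "to", "from", "with", "at", "into", "onto",
             "over", "under", "by", "for", "about", "off", "out", "up",
             "down", "behind", "near"),
    AUX  = c("is", "are", "was", "were", "be", "been", "being", "has",
             "have", "had", "will", "would", "can", "could", "do", "does",
             "did", "may", "might", "shall", "should"),
    CCONJ = c("and", "or", "but"),
    SCONJ = c("because", "while", "if", "when", "as", "since", "although"),
    NUM  = c("one", "two", "three", "four", "five", "six", "seven",
             "eight", "nine", "ten"),
    PART = c("not", "n't"),
    INTJ = c("uh", "um", "oh", "hm", "mhm", "yeah", "yes", "okay", "well"),
    ADV  = c("there", "here", "very", "also", "just", "too", "now", "then",
             "so", "again", "away", "almost", "all"),
    ADJ  = c("little", "big", "small", "busy", "full", "wet", "dirty",
             "good", "fine", "nice", "high", "tall", "empty", "open"),
    VERB = c("see", "sees", "saw", "go", "goes", "going", "get", "gets",
             "getting", "fall", "falls", "falling", "steal", "steals",
             "stealing", "wash", "washes", "washing", "watch", "watches",
             "watching", "take", "takes", "taking", "reach", "reaches",
             "reaching", "stand", "stands", "standing", "run", "runs",
             "running", "dry", "dries", "drying", "overflow", "overflows",
             "overflowing", "spill", "spills", "spilling", "look",
             "looks", "looking", "tip", "tips", "tipping", "hand",
             "hands", "handing", "happen", "happens", "happening",
             "think", "thinks", "know", "knows", "want", "wants")),
  fr = list(
    DET  = c("le", "la", "les", "un", "une", "des", "ce", "cette", "ces",
             "du", "au", "aux", "sa", "son", "ses", "leur", "leurs",
             "ma", "mon", "mes", "l'"),
    PRON = c("il", "elle", "ils", "elles", "je", "tu", "on", "nous",
             "vous", "lui", "leur", "se", "ça", "cela", "qui", "que",
             "y", "en"),
    ADP  = c("dans", "sur", "de", "à", "avec", "pour", "sous", "par",
             "vers", "chez", "devant", "derrière", "près"),
    AUX  = c("est", "sont", "était", "étaient", "a", "ont", "avait",
             "être", "avoir", "sera", "va", "vont", "suis", "es"),
    CCONJ = c("et", "ou", "mais", "donc"),
    SCONJ = c("parce", "quand", "si", "comme", "lorsque"),
    NUM  = c("un", "deux", "trois", "quatre", "cinq", "six", "sept",
             "huit", "neuf", "dix"),
    PART = c("ne", "pas", "n'"),
    INTJ = c("euh", "ben", "bah", "oui", "non", "voilà", "alors", "bon",
             "hein"),
    ADV  = c("là", "ici", "très", "aussi", "trop", "bien", "encore",
             "puis", "tout", "toujours", "déjà", "ailleurs", "beaucoup"),
    ADJ  = c("petit", "petite", "grand", "grande", "occupé", "occupée",
             "plein", "pleine", "mouillé", "mouillée", "sale", "propre",
             "haut", "haute", "ouvert", "ouverte"),
    VERB = c("tombe", "tombent", "tomber", "déborde", "déborder", "coule",
             "couler", "lave", "laver", "sèche", "sécher", "prend",
             "prendre", "prennent", "vole", "voler", "regarde",
             "regarder", "regardent", "voit", "voir", "vois", "essuie",
             "essuyer", "attrape", "attraper", "monte", "monter",
             "renverse", "renverser", "passe", "passer", "fait", "faire",
             "semble", "sembler", "joue", "jouer")))

#' Tag a transcript with the builtin backend
#'
#' Assigns a universal POS tag to every token and a deterministic
#' dependency head: the root of each utterance is its first verb or
#' auxiliary (failing that, its first word token); determiners, adjectives
#' and adpositions attach to the next noun in the utterance, every other
#' token to the root.  Nouns known to the IU lexicon need no special
#' handling because the default tag is NOUN.
#'
#' @param transcript a `speech_transcript`.
#' @param language `"en"` or `"fr"`.
#' @param lexicon optional `iu_lexicon`; its surface forms are tagged NOUN
#'   (single-word forms only).  Purely informative: unknown words default
#'   to NOUN anyway.
#' @return data frame with one row per token: `surface`, `upos`,
#'   `head_offset` (signed token distance to the head, 0 for the root),
#'   `is_word`, `utterance` (index).
#' @export
.tag_lut_cache <- new.env(parent = emptyenv())

tag_lookup <- function(language) {
  lut <- .tag_lut_cache[[language]]
  if (is.null(lut)) {
    lex <- .TAG_LEXICON[[language]]
    # earlier classes win for ambiguous words (e.g. fr "un": DET over NUM)
    order <- c("AUX", "DET", "PRON", "ADP", "CCONJ", "SCONJ", "PART",
               "INTJ", "NUM", "ADV", "ADJ", "VERB")
    words <- unlist(lex[order], use.names = FALSE)
    tags <- rep(order, lengths(lex[order]))
    keep <- !duplicated(words)
    lut <- stats::setNames(tags[keep], words[keep])
    .tag_lut_cache[[language]] <- lut
  }
  lut
}

tag_transcript <- function(transcript, language = c("en", "fr"),
                           lexicon = NULL) {
  language <- match.arg(language)
  lut <- tag_lookup(language)

  surfaces <- character(0); upos_all <- character(0)
  is_word_all <- logical(0); head_off <- numeric(0); utt_idx <- integer(0)
  for (ui in seq_along(transcript$utterances)) {
    u <- transcript$utterances[[ui]]
    n <- nrow(u)
    lt <- tolower(u$surface)
    upos <- unname(lut[lt])
    unknown <- is.na(upos)
    if (any(unknown)) {
      upos[unknown] <- "NOUN"
      if (language == "en")
        upos[unknown & grepl("ing$", lt) & nchar(lt) > 4] <- "VERB"
      upos[unknown & grepl("^[0-9]+$", lt)] <- "NUM"
    }
    upos[!u$is_word] <- "PUNCT"

    verbs <- which(upos %in% c("VERB", "AUX"))
    root <- if (length(verbs)) verbs[1L] else if (any(u$is_word))
      which(u$is_word)[1L] else 1L
    head <- rep.int(root, n)
    nouns <- which(upos %in% c("NOUN", "PROPN", "PRON"))
    for (i in which(upos %in% c("DET", "ADJ", "ADP"))) {
      nxt <- nouns[nouns > i]
      if (length(nxt)) head[i] <- nxt[1L]
    }
    head[root] <- root
    surfaces <- c(surfaces, u$surface)
    upos_all <- c(upos_all, upos)
    is_word_all <- c(is_word_all, u$is_word)
    head_off <- c(head_off, head - seq_len(n))
    utt_idx <- c(utt_idx, rep.int(ui, n))
  }
  data.frame(surface = surfaces, upos = upos_all, head_offset = head_off,
             is_word = is_word_all, utterance = utt_idx,
             stringsAsFactors = FALSE)
}
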
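#' English stopword list
#'
#' The packaged default stopword list: lowercase alphanumeric tokens only
#' (contraction fragments such as "don", "t" are listed separately because
#' the tokenizer splits on the apostrophe). The list identity is recorded in
#' run manifests so a run can be reproduced with the same vocabulary filter.
#'
#' @param id `"english"` for the packaged list, `"none"` for an empty set, or
#'   a path to a one-token-per-line plain-text file.
#' @return character vector of stopword tokens.
#' @export
load_stopwords <- function(id = "english") {
  if (identical(id, "none")) return(character())
  if (identical(id, "english")) {
    path <- system.file("extdata", "stopwords_en.txt", package = "expandnet")
  } else {
    path <- id
    if (!file.exists(path)) stop("no such stopword file: ", path, call. = FALSE)
  }
  words <- readLines(path, encoding = "UTF-8", warn = FALSE)
  words <- trimws(words)
  words[nzchar(words)]
}

#' Normalize free text into tokens
#'
#' The preprocessing recipe applied before any downstream computation, in a
#' fixed order: lowercase, transliterate to ASCII (characters with no
#' decomposition, including emoji, are dropped), split on any non-alphanumeric
#' character, drop empty strings and stopwords. Numerals are kept: product
#' names embed digits. Hashtag-style portmanteaus ("breastcancerawareness")
#' survive as single tokens because only non-alphanumerics split.
#'
#' A total function: any input (including `""` and `NA`) yields a character
#' vector, possibly empty. Idempotent on its own output.
#'
#' @param raw character vector of free text; elements are concatenated.
#' @param stopwords token set to remove; defaults to the packaged English
#'   list. Pass `character()` to keep everything.
#' @return character vector of lowercase ASCII tokens matching `^[a-z0-9]+$`.
#' @export
normalize_text <- function(raw, stopwords = load_stopwords()) {
  raw <- raw[!is.na(raw)]
  if (!length(raw)) return(character())
  x <- paste(raw, collapse = " ")
  x <- tolower(enc2utf8(x))
  # map common Latin diacritics directly (glibc's //TRANSLIT renders them as
  # apostrophe sequences, which would split tokens); anything left that has
  # no ASCII form — emoji, symbols, other scripts — is dropped.
  x <- chartr("áàâäãåçéèêëíìîïñóòôöõøúùûüýÿ",
              "aaaaaaceeeeiiiinooooooouuuuyy", x)
  x <- iconv(x, from = "UTF-8", to = "ASCII", sub = "")
  if (is.na(x)) x <- ""
  tokens <- strsplit(x, "[^a-z0-9]+")[[1]]
  tokens <- tokens[nzchar(tokens)]
  if (length(stopwords)) tokens <- tokens[!(tokens %in% stopwords)]
  tokens
}

#' Tokenize every video in a corpus
#'
#' Produces one token document per video, title first then description, in
#' the corpus row order. All-stopword videos are retained as empty documents
#' rather than silently dropped, so document counts stay aligned with the
#' video table.
#'
#' @param corpus an `expn_corpus`.
#' @param stopwords stopword token set (see [normalize_text()]).
#' @return an object of class `"token_docs"`: a named list (names are video
#'   ids, possibly suffixed for repeated ids across sets) of token vectors,
#'   with a `set_label` attribute aligned to the documents.
#' @export
build_token_docs <- function(corpus, stopwords = load_stopwords()) {
  v <- corpus$videos
  if (!nrow(v)) stop("corpus has no videos", call. = FALSE)
  docs <- lapply(seq_len(nrow(v)), function(i) {
    normalize_text(c(v$title[i], v$description[i]), stopwords = stopwords)
  })
  names(docs) <- make.unique(v$video_id, sep = "#")
  structure(docs, set_label = v$set_label, class = "token_docs")
}

#' @export
print.token_docs <- function(x, ...) {
  n_tok <- sum(lengths(x))
  cat(sprintf("<token_docs> %d documents, %d tokens, %d distinct terms\n",
              length(x), n_tok, length(unique(unlist(x, use.names = FALSE)))))
  invisible(x)
}
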
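#' Does a video's text mention a term?
#'
#' Token-level match after normalization: the term must appear as a whole
#' token in the normalized title-plus-description, so "colonoscopies" does
#' not match "colonoscopy" and case/punctuation are irrelevant. Stopwords
#' are NOT removed before matching, so the check is well defined even for a
#' focal term that happens to be on the stopword list.
#'
#' @param title,description the video's text fields.
#' @param term the (focal) token to look for; nonempty.
#' @return logical.
#' @export
mentions_term <- function(title, description, term) {
  if (!nzchar(term)) stop("term must be nonempty", call. = FALSE)
  tolower(term) %in% normalize_text(c(title, description),
                                    stopwords = character())
}

#' Annotate every video with its focal-term mention flag
#'
#' Fills the cached `mentions_focal` column from [mentions_term()].
#'
#' @param corpus an `expn_corpus`.
#' @param focal focal token; defaults to the corpus focal term.
#' @return the corpus with `mentions_focal` populated.
#' @export
annotate_mentions <- function(corpus, focal = corpus$focal_term) {
  v <- corpus$videos
  v$mentions_focal <- vapply(seq_len(nrow(v)), function(i) {
    mentions_term(v$title[i], v$description[i], focal)
  }, logical(1))
  corpus$videos <- v
  corpus
}

#' Recall-improvement report over expansion terms
#'
#' For each neighbour term's coded sample, tabulates how many videos were
#' coded relevant, how many of those mention the focal term, and how many do
#' not — the latter being the recall improvement: relevant content a
#' focal-term-only search would have missed. Percentages are relative to the
#' coded sample size per term. A `Total` row sums the columns.
#'
#' @param corpus an `expn_corpus` whose expansion videos carry relevance codes.
#' @param focal focal token; defaults to the corpus focal term.
#' @param include_uncoded if `TRUE`, uncoded expansion videos enter the coded
#'   denominator (off by default; the default treats the coded sample as the
#'   population).
#' @return a data.frame of class `"recall_report"` with columns `term`,
#'   `n_coded`, `n_relevant`, `pct_relevant`, `n_relevant_mentioning`,
#'   `pct_mentioning`, `n_relevant_omitting`, `pct_omitting`.
#' @export
recall_improvement <- function(corpus, focal = corpus$focal_term,
                               include_uncoded = FALSE) {
  v <- corpus$videos
  exp_rows <- grepl("^neighbor:", v$set_label)
  coded <- exp_rows & (include_uncoded | v$relevance != "uncoded")
  if (!any(coded)) {
    stop("no coded expansion videos: nothing to report", call. = FALSE)
  }
  v <- v[coded, , drop = FALSE]
  term <- sub("^neighbor:", "", v$set_label)
  mentions <- vapply(seq_len(nrow(v)), function(i) {
    mentions_term(v$title[i], v$description[i], focal)
  }, logical(1))
  rel <- v$relevance == "relevant"

  terms <- sort(unique(term))
  rows <- lapply(terms, function(tm) {
    sel <- term == tm
    data.frame(term = tm,
               n_coded = sum(sel),
               n_relevant = sum(sel & rel),
               n_relevant_mentioning = sum(sel & rel & mentions),
               n_relevant_omitting = sum(sel & rel & !mentions),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- rbind(out, data.frame(term = "Total",
                               n_coded = sum(out$n_coded),
                               n_relevant = sum(out$n_relevant),
                               n_relevant_mentioning = sum(out$n_relevant_mentioning),
                               n_relevant_omitting = sum(out$n_relevant_omitting),
                               stringsAsFactors = FALSE))
  out$pct_relevant <- round_half_up(100 * out$n_relevant / out$n_coded)
  out$pct_mentioning <- round_half_up(100 * out$n_relevant_mentioning / out$n_coded)
  out$pct_omitting <- round_half_up(100 * out$n_relevant_omitting / out$n_coded)
  out <- out[, c("term", "n_coded", "n_relevant", "pct_relevant",
                 "n_relevant_mentioning", "pct_mentioning",
                 "n_relevant_omitting", "pct_omitting")]
  class(out) <- c("recall_report", "data.frame")
  out
}

#' Flag expansion videos already present in the core set
#'
#' A platform search for a neighbour term can return videos the focal-term
#' search already found; such videos are no recall improvement and would
#' double-count in the network evaluation. This marks every expansion row
#' whose `video_id` also occurs in the core set with
#' `exclusion = "duplicate_of_core"`. Nothing is deleted.
#'
#' @param corpus an `expn_corpus`.
#' @return the corpus with duplicates flagged.
#' @export
dedupe_against_core <- function(corpus) {
  v <- corpus$videos
  core <- v$video_id[v$set_label == "core"]
  dup <- grepl("^neighbor:", v$set_label) & v$video_id %in% core
  v$exclusion[dup & v$exclusion == "none"] <- "duplicate_of_core"
  corpus$videos <- v
  corpus
}

# round-half-up (the convention print tables use), to `digits` decimals;
# base round() half-to-even would turn 87.5 into 88 but 88.5 into 88.
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Write a recall report as CSV
#'
#' @param report a `recall_report`.
#' @param path destination.
#' @export
write_recall_report <- function(report, path) {
  utils::write.csv(report, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
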
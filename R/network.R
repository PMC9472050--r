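#' Exclusion filter for the network evaluation
#'
#' Before degree statistics are meaningful, the coded expansion sample must
#' drop (1) videos with missing metadata, (2) videos already present in the
#' core set (see [dedupe_against_core()]) and (3) non-English videos, which
#' a monolingual core set cannot connect to. Each video gets at most one
#' exclusion reason, assigned in that priority order. Nothing is deleted:
#' the function returns the retained expansion ids and a per-reason tally.
#'
#' @param corpus an `expn_corpus`; run [dedupe_against_core()] first if
#'   duplicates may be present.
#' @param treat_und_as_non_english should language `"und"` count as
#'   non-English? Default `FALSE` (trust the provided tag).
#' @return list with `retained` (character ids, expansion videos that
#'   survive), `videos` (the retained expansion rows), and `tally` (named
#'   integer vector over exclusion reasons, including `retained`).
#' @export
exclusion_filter <- function(corpus, treat_und_as_non_english = FALSE) {
  v <- corpus$videos
  # the evaluation population is the coded expansion sample
  ex <- v[grepl("^neighbor:", v$set_label) & v$relevance != "uncoded", ,
          drop = FALSE]
  non_en <- !grepl("^en", ex$language) &
    (treat_und_as_non_english | ex$language != "und")
  reason <- rep("none", nrow(ex))
  reason[non_en] <- "non_english"
  reason[ex$exclusion == "duplicate_of_core"] <- "duplicate_of_core"
  reason[ex$exclusion == "missing_metadata"] <- "missing_metadata"
  keep <- reason == "none"
  if (!any(keep)) warning("exclusion filter retained no videos", call. = FALSE)
  tally <- c(retained = sum(keep),
             non_english = sum(reason == "non_english"),
             duplicate_of_core = sum(reason == "duplicate_of_core"),
             missing_metadata = sum(reason == "missing_metadata"))
  list(retained = ex$video_id[keep],
       videos = ex[keep, , drop = FALSE],
       tally = tally)
}

#' Degree of expansion videos with respect to the core set
#'
#' Counts, for every retained expansion video, the distinct directed
#' relatedness edges linking it to the core set: `indegree` (core -> video),
#' `outdegree` (video -> core) and their sum `total_degree`, the filtering
#' statistic. Edges between two core videos, between two expansion videos,
#' or touching unknown ids are ignored. The two sets must be disjoint —
#' flag and filter duplicates first.
#'
#' @param edges edge data.frame (`source_id`, `target_id`).
#' @param core_ids,new_ids disjoint character id sets.
#' @return data.frame with one row per `new_ids` entry (zeros included):
#'   `video_id`, `indegree`, `outdegree`, `total_degree`.
#' @export
degree_metrics <- function(edges, core_ids, new_ids) {
  if (length(intersect(core_ids, new_ids))) {
    stop("core and new id sets overlap; run dedupe/exclusion first",
         call. = FALSE)
  }
  edges <- normalize_edges(edges)
  core_to_new <- edges$source_id %in% core_ids & edges$target_id %in% new_ids
  new_to_core <- edges$source_id %in% new_ids & edges$target_id %in% core_ids
  indeg <- table(factor(edges$target_id[core_to_new], levels = new_ids))
  outdeg <- table(factor(edges$source_id[new_to_core], levels = new_ids))
  data.frame(video_id = new_ids,
             indegree = as.integer(indeg),
             outdegree = as.integer(outdeg),
             total_degree = as.integer(indeg) + as.integer(outdeg),
             stringsAsFactors = FALSE)
}

#' Cumulative precision/recall/F1 curve over degree thresholds
#'
#' Orders the observed total-degree values descending and accumulates video
#' and relevant-video counts from the best-connected videos down. Each row
#' reports, for the threshold "degree >= this row's degree": cumulative
#' precision (cumulative relevant / cumulative videos), cumulative recall
#' (cumulative relevant / total relevant) and their harmonic mean F1. Only
#' observed degree values get rows; the last row (smallest observed degree,
#' typically 0) always has 100% recall.
#'
#' Percentages are carried at full precision; the conventional display
#' rounding (precision to integer, recall and F1 to one decimal, F1 computed
#' from unrounded inputs) is applied by [format()] / [write_threshold_curve()].
#'
#' @param records degree data.frame from [degree_metrics()].
#' @param relevance named logical (or a vector of ids coded relevant):
#'   relevance code per retained video.
#' @return data.frame of class `"threshold_curve"` with columns `degree`,
#'   `n_videos`, `n_relevant`, `pct_relevant`, `cum_videos`, `cum_relevant`,
#'   `cum_precision`, `cum_recall`, `cum_f1`; attribute `total_relevant`.
#' @export
threshold_curve <- function(records, relevance) {
  if (!nrow(records)) stop("no degree records", call. = FALSE)
  if (is.character(relevance)) {
    relevance <- stats::setNames(records$video_id %in% relevance,
                                 records$video_id)
  }
  miss <- setdiff(records$video_id, names(relevance))
  if (length(miss)) {
    stop("no relevance code for: ", paste(utils::head(miss, 3), collapse = ", "),
         call. = FALSE)
  }
  rel <- as.logical(relevance[records$video_id])
  total_relevant <- sum(rel)
  if (total_relevant == 0) {
    stop("zero relevant videos overall: recall is undefined", call. = FALSE)
  }
  degs <- sort(unique(records$total_degree), decreasing = TRUE)
  n_videos <- vapply(degs, function(g) sum(records$total_degree == g), 1L)
  n_rel <- vapply(degs, function(g) sum(rel & records$total_degree == g), 1L)
  cum_videos <- cumsum(n_videos)
  cum_rel <- cumsum(n_rel)
  p <- 100 * cum_rel / cum_videos
  r <- 100 * cum_rel / total_relevant
  f1 <- ifelse(p + r == 0, 0, 2 * p * r / (p + r))
  out <- data.frame(degree = degs, n_videos = n_videos, n_relevant = n_rel,
                    pct_relevant = 100 * n_rel / n_videos,
                    cum_videos = cum_videos, cum_relevant = cum_rel,
                    cum_precision = p, cum_recall = r, cum_f1 = f1)
  attr(out, "total_relevant") <- total_relevant
  class(out) <- c("threshold_curve", "data.frame")
  out
}

#' @export
format.threshold_curve <- function(x, ...) {
  data.frame(degree = x$degree, n_videos = x$n_videos,
             n_relevant = x$n_relevant,
             pct_relevant = round_half_up(x$pct_relevant),
             cum_videos = x$cum_videos, cum_relevant = x$cum_relevant,
             cum_precision = round_half_up(x$cum_precision),
             cum_recall = round_half_up(x$cum_recall, 1),
             cum_f1 = round_half_up(x$cum_f1, 1))
}

#' @export
print.threshold_curve <- function(x, ...) {
  cat(sprintf("<threshold_curve> %d rows, %d retained videos, %d relevant\n",
              nrow(x), max(x$cum_videos), attr(x, "total_relevant")))
  print(format(x))
  invisible(x)
}

#' Write a threshold curve as CSV (display rounding applied)
#'
#' @param curve a `threshold_curve`.
#' @param path destination.
#' @export
write_threshold_curve <- function(curve, path) {
  utils::write.csv(format(curve), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Cumulative statistics at a degree threshold
#'
#' Reads the curve row for the smallest observed degree `>= min_degree` —
#' i.e. the statistics a coding team would face if it only inspected videos
#' with at least that many connections to the core set.
#'
#' @param curve a `threshold_curve`.
#' @param min_degree nonnegative integer threshold.
#' @return list with `precision`, `recall`, `f1` (unrounded percentages),
#'   `n` (videos at or above the threshold) and `n_relevant`.
#' @export
precision_at <- function(curve, min_degree) {
  ok <- curve$degree >= min_degree
  if (!any(ok)) {
    stop("min_degree ", min_degree, " exceeds the maximum observed degree ",
         max(curve$degree), call. = FALSE)
  }
  row <- curve[max(which(ok)), ]
  list(precision = row$cum_precision, recall = row$cum_recall,
       f1 = row$cum_f1, n = row$cum_videos, n_relevant = row$cum_relevant)
}
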
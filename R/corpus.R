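#' @useDynLib expandnet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

VIDEO_COLUMNS <- c("video_id", "title", "description", "published_at",
                   "language", "set_label", "relevance", "mentions_focal",
                   "exclusion")

RELEVANCE_LEVELS <- c("relevant", "irrelevant", "uncoded")
EXCLUSION_LEVELS <- c("none", "non_english", "duplicate_of_core",
                      "missing_metadata")

#' Construct a video record data frame
#'
#' One row per video, carrying identifiers, the title/description text used
#' throughout the pipeline, the set label (`"core"` for videos retrieved with
#' the focal term, `"neighbor:<term>"` for videos retrieved with an expansion
#' term), a relevance code (human coding is an input, not something this
#' package performs) and an exclusion reason.
#'
#' @param video_id character, nonempty, unique within each set label.
#' @param title,description free text; either may be empty.
#' @param published_at optional timestamp string ("" if unknown).
#' @param language IETF-style tag; `"und"` when undetermined.
#' @param set_label `"core"` or `"neighbor:<term>"` with a nonempty term.
#' @param relevance one of `"relevant"`, `"irrelevant"`, `"uncoded"`.
#' @param exclusion one of `"none"`, `"non_english"`, `"duplicate_of_core"`,
#'   `"missing_metadata"`.
#' @return a data.frame with the canonical video columns.
#' @export
video_records <- function(video_id, title = "", description = "",
                          published_at = "", language = "en",
                          set_label = "core", relevance = "uncoded",
                          exclusion = "none") {
  n <- length(video_id)
  df <- data.frame(
    video_id = as.character(video_id),
    title = rep_len(as.character(title), n),
    description = rep_len(as.character(description), n),
    published_at = rep_len(as.character(published_at), n),
    language = rep_len(as.character(language), n),
    set_label = rep_len(as.character(set_label), n),
    relevance = rep_len(as.character(relevance), n),
    mentions_focal = rep_len(NA, n),
    exclusion = rep_len(as.character(exclusion), n),
    stringsAsFactors = FALSE
  )
  df
}

validate_videos <- function(videos) {
  missing_cols <- setdiff(VIDEO_COLUMNS, names(videos))
  if (length(missing_cols)) {
    stop("video table is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (any(is.na(videos$video_id) | videos$video_id == "")) {
    stop("every video record needs a nonempty video_id", call. = FALSE)
  }
  key <- paste(videos$video_id, videos$set_label, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- videos$video_id[duplicated(key)][1]
    stop("duplicate video_id within a set: ", dup, call. = FALSE)
  }
  bad_rel <- setdiff(unique(videos$relevance), RELEVANCE_LEVELS)
  if (length(bad_rel)) {
    stop("unknown relevance code(s): ", paste(bad_rel, collapse = ", "),
         call. = FALSE)
  }
  bad_exc <- setdiff(unique(videos$exclusion), EXCLUSION_LEVELS)
  if (length(bad_exc)) {
    stop("unknown exclusion code(s): ", paste(bad_exc, collapse = ", "),
         call. = FALSE)
  }
  neigh <- grepl("^neighbor:", videos$set_label)
  ok <- videos$set_label == "core" |
    (neigh & nchar(sub("^neighbor:", "", videos$set_label)) > 0)
  if (!all(ok)) {
    stop("set_label must be \"core\" or \"neighbor:<term>\" with a nonempty term",
         call. = FALSE)
  }
  invisible(videos)
}

#' Construct a corpus
#'
#' A corpus bundles the video metadata table, the directed relatedness edge
#' list and the focal term. Edge endpoints that do not resolve to a known
#' video are retained but marked `external = TRUE`; degree computations
#' ignore them (a platform crawl routinely returns edges to unretrieved
#' videos).
#'
#' @param videos a data.frame as built by [video_records()].
#' @param edges a data.frame with columns `source_id`, `target_id` (deduplicated,
#'   self-loops dropped). May be empty.
#' @param focal_term the technical seed term the corpus was built around.
#' @return an object of class `"expn_corpus"`.
#' @export
corpus <- function(videos, edges = NULL, focal_term = "") {
  validate_videos(videos)
  if (is.null(edges)) {
    edges <- data.frame(source_id = character(), target_id = character(),
                        stringsAsFactors = FALSE)
  }
  edges <- normalize_edges(edges)
  known <- unique(videos$video_id)
  edges$external <- !(edges$source_id %in% known & edges$target_id %in% known)
  obj <- structure(
    list(videos = videos, edges = edges, focal_term = as.character(focal_term)),
    class = "expn_corpus"
  )
  obj
}

normalize_edges <- function(edges) {
  if (!all(c("source_id", "target_id") %in% names(edges))) {
    stop("edge table needs columns source_id and target_id", call. = FALSE)
  }
  edges$source_id <- as.character(edges$source_id)
  edges$target_id <- as.character(edges$target_id)
  keep <- edges$source_id != edges$target_id
  edges <- edges[keep, , drop = FALSE]
  key <- paste(edges$source_id, edges$target_id, sep = "\r")
  edges <- edges[!duplicated(key), c("source_id", "target_id"), drop = FALSE]
  rownames(edges) <- NULL
  edges
}

#' @export
print.expn_corpus <- function(x, ...) {
  sets <- table(x$videos$set_label)
  cat(sprintf("<expn_corpus> %d videos, %d edges, focal term \"%s\"\n",
              nrow(x$videos), nrow(x$edges), x$focal_term))
  for (s in names(sets)) cat(sprintf("  %-24s %d\n", s, sets[[s]]))
  invisible(x)
}

#' Core and expansion video ids
#'
#' @param corpus an `expn_corpus`.
#' @return character vector of video ids.
#' @export
core_ids <- function(corpus) {
  unique(corpus$videos$video_id[corpus$videos$set_label == "core"])
}

#' @rdname core_ids
#' @export
expansion_ids <- function(corpus) {
  unique(corpus$videos$video_id[grepl("^neighbor:", corpus$videos$set_label)])
}

#' Read a video corpus from disk
#'
#' JSON Lines is the canonical dialect (one video object per line, UTF-8);
#' CSV is supported with quoted text fields. Records must carry at least
#' `video_id`, `title`, `description` and `set_label`; the remaining columns
#' default sensibly.
#'
#' @param path corpus file.
#' @param format `"jsonl"` or `"csv"`; guessed from the extension by default.
#' @param edges optional edge data.frame or path to an edge list file.
#' @param focal_term the focal term; read from a `focal_term` field on the
#'   records when present and not given here.
#' @return an `expn_corpus`.
#' @export
read_corpus <- function(path, format = c("auto", "jsonl", "csv"),
                        edges = NULL, focal_term = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such corpus file: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "jsonl"
  }
  if (format == "jsonl") {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) stop("empty corpus file: ", path, call. = FALSE)
    recs <- vector("list", length(lines))
    for (i in seq_along(lines)) {
      rec <- tryCatch(jsonlite::fromJSON(lines[[i]]),
                      error = function(e) {
                        stop(sprintf("parse error at line %d of %s: %s",
                                     i, path, conditionMessage(e)), call. = FALSE)
                      })
      if (is.null(rec$video_id) || !nzchar(rec$video_id)) {
        stop(sprintf("parse error at line %d of %s: missing video_id", i, path),
             call. = FALSE)
      }
      recs[[i]] <- rec
    }
    df <- do.call(rbind, lapply(recs, record_to_row))
    fts <- unlist(lapply(recs, `[[`, "focal_term"))
    if (length(fts)) attr(df, "focal_term") <- fts[[1]]
  } else {
    df0 <- utils::read.csv(path, stringsAsFactors = FALSE,
                           colClasses = "character", encoding = "UTF-8")
    if (is.null(df0$video_id)) stop("csv corpus lacks a video_id column", call. = FALSE)
    if (any(!nzchar(df0$video_id))) {
      stop(sprintf("parse error at row %d of %s: missing video_id",
                   which(!nzchar(df0$video_id))[1], path), call. = FALSE)
    }
    df <- do.call(rbind, lapply(seq_len(nrow(df0)),
                                function(i) record_to_row(as.list(df0[i, ]))))
    if (!is.null(df0$focal_term)) attr(df, "focal_term") <- df0$focal_term[[1]]
  }
  if (is.null(focal_term)) {
    focal_term <- attr(df, "focal_term")
    if (is.null(focal_term)) focal_term <- ""
  }
  attr(df, "focal_term") <- NULL
  if (is.character(edges) && length(edges) == 1) edges <- read_edges(edges)
  corpus(df, edges = edges, focal_term = focal_term)
}

record_to_row <- function(rec) {
  get <- function(field, default) {
    v <- rec[[field]]
    if (is.null(v) || length(v) != 1 || is.na(v)) default else as.character(v)
  }
  row <- data.frame(
    video_id = get("video_id", NA_character_),
    title = get("title", ""),
    description = get("description", ""),
    published_at = get("published_at", ""),
    language = get("language", "und"),
    set_label = get("set_label", "core"),
    relevance = get("relevance", "uncoded"),
    mentions_focal = suppressWarnings(as.logical(get("mentions_focal", NA))),
    exclusion = get("exclusion", "none"),
    stringsAsFactors = FALSE
  )
  row
}

#' Write a corpus to disk
#'
#' The JSONL writer emits one object per video, with the focal term recorded
#' on each record so that `read_corpus(write_corpus(x))` round-trips.
#'
#' @param corpus an `expn_corpus`.
#' @param path destination for the video table.
#' @param format `"jsonl"` or `"csv"`.
#' @param edges_path optional destination for the edge list (TSV).
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path, format = c("jsonl", "csv"),
                         edges_path = NULL) {
  format <- match.arg(format)
  v <- corpus$videos
  if (format == "jsonl") {
    con <- file(path, open = "wb")
    on.exit(close(con))
    for (i in seq_len(nrow(v))) {
      rec <- as.list(v[i, VIDEO_COLUMNS])
      rec$focal_term <- corpus$focal_term
      if (is.na(rec$mentions_focal)) rec$mentions_focal <- NULL
      writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, null = "null"),
                 con, useBytes = TRUE)
    }
  } else {
    out <- v[, VIDEO_COLUMNS]
    out$focal_term <- corpus$focal_term
    utils::write.csv(out, path, row.names = FALSE, fileEncoding = "UTF-8")
  }
  if (!is.null(edges_path)) write_edges(corpus$edges, edges_path)
  invisible(path)
}

#' Read a directed relatedness edge list
#'
#' Expects two id columns (`source_id`, `target_id`), tab- or
#' comma-separated, with or without a header. Duplicate directed edges are
#' collapsed and self-loops dropped (a message reports how many).
#'
#' @param path edge list file.
#' @return a data.frame with columns `source_id`, `target_id`.
#' @export
read_edges <- function(path) {
  if (!file.exists(path)) stop("no such edge file: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    return(data.frame(source_id = character(), target_id = character(),
                      stringsAsFactors = FALSE))
  }
  sep <- if (grepl("\t", lines[[1]])) "\t" else ","
  parts <- strsplit(lines, sep, fixed = TRUE)
  bad <- which(vapply(parts, length, 1L) != 2L)
  if (length(bad)) {
    stop(sprintf("parse error at line %d of %s: expected 2 columns", bad[1], path),
         call. = FALSE)
  }
  m <- do.call(rbind, parts)
  df <- data.frame(source_id = trimws(m[, 1]), target_id = trimws(m[, 2]),
                   stringsAsFactors = FALSE)
  if (identical(tolower(df$source_id[1]), "source_id")) df <- df[-1, , drop = FALSE]
  n0 <- nrow(df)
  loops <- sum(df$source_id == df$target_id)
  df <- normalize_edges(df)
  dropped <- n0 - nrow(df)
  if (dropped > 0) {
    message(sprintf("read_edges: dropped %d self-loop(s) and %d duplicate edge(s)",
                    loops, dropped - loops))
  }
  df
}

#' @rdname read_edges
#' @param edges edge data.frame.
#' @param path destination (TSV with header).
#' @export
write_edges <- function(edges, path) {
  utils::write.table(edges[, c("source_id", "target_id")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run configuration
#'
#' Flat bag of run parameters shared by the pipeline stages: the focal term,
#' how many neighbour terms to expand with, embedding hyperparameters, the
#' stopword list id and the degree threshold of interest.
#'
#' @param focal_term token the run expands around.
#' @param k_neighbors how many nearest-neighbour terms to use (>= 1).
#' @param dim,window,epochs,min_count,algorithm,negative embedding
#'   hyperparameters; see [train_embeddings()].
#' @param seed integer seed funnelled to every random stage.
#' @param stopwords stopword list id (currently `"english"`) or a path to a
#'   one-token-per-line file.
#' @param min_degree degree threshold for the precision summary.
#' @param treat_und_as_non_english should language `"und"` be excluded as
#'   non-English? Default trusts the provided tag.
#' @return a list of class `"expn_config"`.
#' @export
run_config <- function(focal_term = "colonoscopy", k_neighbors = 6L,
                       dim = 50L, window = 5L, epochs = 5L, min_count = 5L,
                       algorithm = c("skipgram", "cbow"), negative = 5L,
                       seed = 1L, stopwords = "english", min_degree = 1L,
                       treat_und_as_non_english = FALSE) {
  algorithm <- match.arg(algorithm)
  cfg <- list(focal_term = focal_term, k_neighbors = as.integer(k_neighbors),
              dim = as.integer(dim), window = as.integer(window),
              epochs = as.integer(epochs), min_count = as.integer(min_count),
              algorithm = algorithm, negative = as.integer(negative),
              seed = as.integer(seed), stopwords = stopwords,
              min_degree = as.integer(min_degree),
              treat_und_as_non_english = isTRUE(treat_und_as_non_english))
  if (cfg$k_neighbors < 1) stop("k_neighbors must be >= 1", call. = FALSE)
  if (cfg$dim < 2) stop("embedding dim must be >= 2", call. = FALSE)
  if (cfg$min_count < 1) stop("min_count must be >= 1", call. = FALSE)
  class(cfg) <- "expn_config"
  cfg
}

#' Read a flat key = value configuration file
#'
#' Lines of the form `key = value` (TOML-style scalars; `#` comments).
#' Unknown keys are an error so typos surface early.
#'
#' @param path config file.
#' @return an `expn_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([A-Za-z_][A-Za-z0-9_]*)\\s*=\\s*(.*)$", lines))
  bad <- which(vapply(kv, length, 1L) != 3L)
  if (length(bad)) stop("bad config line: ", lines[bad[1]], call. = FALSE)
  vals <- lapply(kv, function(m) {
    v <- gsub("^\"|\"$", "", m[[3]])
    if (grepl("^-?[0-9]+$", v)) v <- as.integer(v)
    else if (grepl("^-?[0-9.]+$", v)) v <- as.numeric(v)
    else if (v %in% c("true", "false")) v <- v == "true"
    v
  })
  names(vals) <- vapply(kv, `[[`, "", 2L)
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  do.call(run_config, vals)
}

#' @rdname read_run_config
#' @param config an `expn_config`.
#' @export
write_run_config <- function(config, path) {
  fmt <- function(v) {
    if (is.character(v)) sprintf('"%s"', v)
    else if (is.logical(v)) tolower(as.character(v))
    else as.character(v)
  }
  writeLines(sprintf("%s = %s", names(config),
                     vapply(unclass(config), fmt, "")), path)
  invisible(path)
}
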
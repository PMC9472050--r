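#' Configuration for the synthetic corpus generator
#'
#' The generator emulates the data a focal-term retrieval plus
#' neighbour-term expansion would produce on a video platform: a core set of
#' videos retrieved with the technical focal term, per-neighbour-term
#' expansion sets with human relevance codes, and a directed relatedness
#' graph in which relevant expansion videos connect to the core set far more
#' often than irrelevant ones. Text is a mixture of unigram topic
#' distributions (one focal-preparation topic plus background topics); no
#' grammar is modelled.
#'
#' Defaults mirror the scale and rates of a published colonoscopy case
#' study: a 250-video core set, 6 brand-like neighbour terms with 25 coded
#' videos each (150 coded), ~34% of coded expansion videos relevant, ~59% of
#' relevant ones mentioning the focal term, ~19% non-English, ~5% duplicates
#' of core videos, ~0.7% with missing metadata, and per-core-video edge
#' probabilities chosen so that roughly 80% of relevant but under 20% of
#' irrelevant expansion videos have at least one connection to the core set.
#'
#' @param n_core core set size.
#' @param n_expansion_per_term videos retrieved per neighbour term (the full
#'   expansion set; all of them feed the embedding corpus).
#' @param n_coded_per_term how many videos per term carry human relevance
#'   codes (a random subsample, as when a coding team codes 10% of each
#'   set); capped at `n_expansion_per_term`. Exclusion bookkeeping, recall
#'   and network evaluation operate on this coded sample.
#' @param focal_term the technical seed token.
#' @param planted_neighbor_terms brand-like tokens planted to co-occur with
#'   the focal term; each also names an expansion set.
#' @param background_vocab_size total background vocabulary size, split over
#'   `n_background_topics` disjoint topics.
#' @param n_background_topics number of background (irrelevant) topics.
#' @param title_len,desc_len integer ranges (min, max) of title and
#'   description token counts.
#' @param p_focal_cooccur probability a core video's text carries a planted
#'   neighbour term next to the focal term (the co-occurrence signal the
#'   embedding must pick up).
#' @param p_relevant probability a coded expansion video is relevant.
#' @param p_mention probability a relevant expansion video mentions the
#'   focal term.
#' @param p_edge_rel,p_edge_irr per-core-video probability of a relatedness
#'   edge for relevant / irrelevant expansion videos (direction uniform).
#'   Recovery of the precision gain needs `p_edge_rel >= p_edge_irr`.
#' @param p_non_english probability an expansion video is non-English
#'   (disjoint vocabulary, no forced edges).
#' @param p_duplicate probability an expansion video is a copy of a core
#'   video.
#' @param p_missing_metadata probability the platform returns no metadata.
#' @return list of class `"expn_genconfig"`.
#' @export
generator_config <- function(n_core = 250L, n_expansion_per_term = 250L,
                             n_coded_per_term = 25L,
                             focal_term = "colonoscopy",
                             planted_neighbor_terms = c("suprep", "peg",
                               "sutab", "plenvu", "glycol", "miralax"),
                             background_vocab_size = 200L,
                             n_background_topics = 3L,
                             title_len = c(4L, 10L), desc_len = c(20L, 60L),
                             p_focal_cooccur = 0.6,
                             p_relevant = 0.34, p_mention = 0.59,
                             p_edge_rel = 0.0065, p_edge_irr = 0.00075,
                             p_non_english = 0.187, p_duplicate = 0.053,
                             p_missing_metadata = 0.007) {
  cfg <- list(n_core = as.integer(n_core),
              n_expansion_per_term = as.integer(n_expansion_per_term),
              n_coded_per_term = min(as.integer(n_coded_per_term),
                                     as.integer(n_expansion_per_term)),
              focal_term = focal_term,
              planted_neighbor_terms = planted_neighbor_terms,
              background_vocab_size = as.integer(background_vocab_size),
              n_background_topics = as.integer(n_background_topics),
              title_len = as.integer(title_len), desc_len = as.integer(desc_len),
              p_focal_cooccur = p_focal_cooccur,
              p_relevant = p_relevant, p_mention = p_mention,
              p_edge_rel = p_edge_rel, p_edge_irr = p_edge_irr,
              p_non_english = p_non_english, p_duplicate = p_duplicate,
              p_missing_metadata = p_missing_metadata)
  probs <- unlist(cfg[grep("^p_", names(cfg))])
  if (any(probs < 0 | probs > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$n_core < 1 || cfg$n_expansion_per_term < 1 ||
      cfg$n_coded_per_term < 1) {
    stop("counts must be positive", call. = FALSE)
  }
  if (!nzchar(cfg$focal_term) || !length(cfg$planted_neighbor_terms)) {
    stop("focal term and planted neighbour terms are required", call. = FALSE)
  }
  class(cfg) <- "expn_genconfig"
  cfg
}

# Vocabulary shared between focal-topic and background documents. Real
# corpora have no words (other than brands and the focal term itself) that
# occur *only* next to the focal term: "doctor" or "prep" also appear in
# unrelated videos. Background topics therefore mix their own tokens with
# this general vocabulary, which leaves the planted brand terms as the only
# tokens whose contexts are almost purely focal — the structure that puts
# them at the top of the neighbour ranking, as observed on real platforms.
GENERAL_WORDS <- c("prep", "bowel", "clean", "cleanse", "doctor", "clinic",
                   "kit", "procedure", "screening", "drink", "liquid",
                   "dose", "instructions", "experience", "tips",
                   "hospital", "nurse", "schedule", "fasting", "results",
                   "polyp", "colon", "scope", "video", "channel", "watch",
                   "subscribe", "review", "day", "week", "morning", "easy",
                   "guide", "story", "time", "best", "health", "life")

#' Generate a synthetic video corpus with known ground truth
#'
#' Deterministic given `(config, seed)`. Core videos always mention the
#' focal term; relevant expansion videos draw from the focal topic and
#' mention it with probability `p_mention`; irrelevant ones draw from a
#' background topic (but contain their neighbour term — that is why the
#' platform returned them). Relatedness edges between English, non-duplicate
#' expansion videos and core videos are independent Bernoulli draws with
#' direction chosen uniformly; non-English videos get no edges. The planted
#' parameters are recorded in a `ground_truth` attribute for recovery tests
#' (see [ground_truth_report()]).
#'
#' @param config an `expn_genconfig`.
#' @param seed integer seed.
#' @return an `expn_corpus` with relevance codes on expansion videos and a
#'   `ground_truth` attribute.
#' @export
generate_corpus <- function(config = generator_config(), seed = 1L) {
  if (!inherits(config, "expn_genconfig")) {
    stop("config must come from generator_config()", call. = FALSE)
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(as.integer(seed))

  terms <- config$planted_neighbor_terms
  bg_per_topic <- max(5L, config$background_vocab_size %/% config$n_background_topics)
  bg_topics <- lapply(seq_len(config$n_background_topics), function(t) {
    sprintf("bg%dword%02d", t, seq_len(bg_per_topic))
  })
  xx_vocab <- sprintf("fremd%02d", 1:40)

  rlen <- function(rng) sample(rng[1]:rng[2], 1)
  focal_doc <- function(n) sample(GENERAL_WORDS, n, replace = TRUE)
  bg_doc <- function(n, topic) {
    # background docs are half topic-specific, half general vocabulary
    own <- stats::rbinom(1, n, 0.5)
    sample(c(sample(topic, own, replace = TRUE),
             sample(GENERAL_WORDS, n - own, replace = TRUE)))
  }

  make_core <- function(i) {
    co <- stats::runif(1) < config$p_focal_cooccur
    planted <- if (co) sample(terms, 1) else NULL
    title <- c(config$focal_term, planted, focal_doc(max(1, rlen(config$title_len) - 1 - length(planted))))
    desc <- focal_doc(rlen(config$desc_len))
    if (co) {
      # prep-instruction descriptions repeat the brand and the focal term in
      # a dense run ("suprep colonoscopy prep ... take suprep ..."); plant an
      # alternating block so the pair co-occurs inside one context window
      block <- rep(c(planted, config$focal_term), 3)
      pos <- sample(seq_along(desc), 1)
      desc <- append(desc, block, after = pos)
    }
    list(video_id = sprintf("core%04d", i),
         title = paste(title, collapse = " "),
         description = paste(desc, collapse = " "),
         language = "en", set_label = "core", relevance = "uncoded",
         exclusion = "none", status = "core", true_relevant = NA)
  }

  make_expansion <- function(tm, i, core_pool, used_dup) {
    u <- stats::runif(1)
    status <-
      if (u < config$p_duplicate) "duplicate"
      else if (u < config$p_duplicate + config$p_missing_metadata) "missing"
      else if (u < config$p_duplicate + config$p_missing_metadata +
               config$p_non_english) "non_english"
      else "normal"
    if (status == "duplicate" && length(used_dup) >= length(core_pool)) {
      status <- "normal"            # cannot duplicate the same core video twice
    }
    if (status == "duplicate") {
      pick <- sample(setdiff(seq_along(core_pool), used_dup), 1)
      src <- core_pool[[pick]]
      attr(src, "core_index") <- pick
      return(list(video_id = src$video_id, title = src$title,
                  description = src$description, language = "en",
                  set_label = paste0("neighbor:", tm), relevance = "relevant",
                  exclusion = "none", status = "duplicate",
                  true_relevant = TRUE, core_index = pick))
    }
    relevant <- stats::runif(1) < config$p_relevant
    if (status == "missing") {
      return(list(video_id = sprintf("vid_%s_%03d", tm, i), title = "",
                  description = "", language = "en",
                  set_label = paste0("neighbor:", tm),
                  relevance = if (relevant) "relevant" else "irrelevant",
                  exclusion = "missing_metadata", status = "missing",
                  true_relevant = relevant))
    }
    if (status == "non_english") {
      words <- sample(xx_vocab, rlen(config$desc_len), replace = TRUE)
      return(list(video_id = sprintf("vid_%s_%03d", tm, i),
                  title = paste(sample(xx_vocab, rlen(config$title_len)),
                                collapse = " "),
                  description = paste(words, collapse = " "),
                  language = sample(c("es", "de", "pt"), 1),
                  set_label = paste0("neighbor:", tm),
                  relevance = if (relevant) "relevant" else "irrelevant",
                  exclusion = "none", status = "non_english",
                  true_relevant = relevant))
    }
    if (relevant) {
      mention <- stats::runif(1) < config$p_mention
      title <- c(tm, if (mention) config$focal_term,
                 focal_doc(max(1, rlen(config$title_len) - 1 - mention)))
      desc <- c(focal_doc(rlen(config$desc_len)), tm)
      if (mention) desc <- append(desc, c(tm, config$focal_term, tm),
                                  after = sample(seq_along(desc), 1))
    } else {
      # platform search is fuzzy: an irrelevant video retrieved for a brand
      # query usually does not carry the brand token in its own text
      topic <- bg_topics[[sample(config$n_background_topics, 1)]]
      title <- bg_doc(max(1, rlen(config$title_len)), topic)
      desc <- bg_doc(rlen(config$desc_len), topic)
      if (stats::runif(1) < 0.15) desc <- c(desc, tm)
    }
    list(video_id = sprintf("vid_%s_%03d", tm, i),
         title = paste(title, collapse = " "),
         description = paste(desc, collapse = " "),
         language = "en", set_label = paste0("neighbor:", tm),
         relevance = if (relevant) "relevant" else "irrelevant",
         exclusion = "none", status = "normal", true_relevant = relevant)
  }

  core <- lapply(seq_len(config$n_core), make_core)
  expn <- list()
  for (tm in terms) {
    used_dup <- integer()
    coded_idx <- sort(sample(config$n_expansion_per_term,
                             config$n_coded_per_term))
    for (i in seq_len(config$n_expansion_per_term)) {
      r <- make_expansion(tm, i, core, used_dup)
      if (r$status == "duplicate") used_dup <- c(used_dup, r$core_index)
      r$coded <- i %in% coded_idx
      if (!r$coded) r$relevance <- "uncoded"
      expn[[length(expn) + 1]] <- r
    }
  }
  recs <- c(core, expn)
  videos <- do.call(rbind, lapply(recs, function(r) {
    video_records(r$video_id, title = r$title, description = r$description,
                  language = r$language, set_label = r$set_label,
                  relevance = r$relevance, exclusion = r$exclusion)
  }))

  # relatedness edges: expansion <-> core, Bernoulli per pair, random
  # direction; queried only for the coded sample (as a coding team would)
  core_ids <- vapply(core, `[[`, "", "video_id")
  src <- character(); dst <- character()
  for (r in expn) {
    if (!r$coded || r$status %in% c("duplicate", "non_english", "missing")) next
    p <- if (isTRUE(r$true_relevant)) config$p_edge_rel else config$p_edge_irr
    hit <- which(stats::runif(length(core_ids)) < p)
    if (!length(hit)) next
    flip <- stats::runif(length(hit)) < 0.5
    src <- c(src, ifelse(flip, core_ids[hit], r$video_id))
    dst <- c(dst, ifelse(flip, r$video_id, core_ids[hit]))
  }
  edges <- data.frame(source_id = src, target_id = dst, stringsAsFactors = FALSE)

  status <- vapply(expn, `[[`, "", "status")
  coded <- vapply(expn, `[[`, TRUE, "coded")
  truly_rel <- vapply(expn, function(r) isTRUE(r$true_relevant), TRUE)
  truth <- list(
    seed = as.integer(seed), config = config,
    n_core = length(core), n_expansion = length(expn),
    n_coded = sum(coded),
    n_duplicate = sum(coded & status == "duplicate"),
    n_missing_metadata = sum(coded & status == "missing"),
    n_non_english = sum(coded & status == "non_english"),
    n_retained = sum(coded & status == "normal"),
    n_relevant_retained = sum(coded & status == "normal" & truly_rel),
    relevance_rate_retained = mean(truly_rel[coded & status == "normal"]),
    planted_terms = terms
  )

  out <- corpus(videos, edges = edges, focal_term = config$focal_term)
  attr(out, "ground_truth") <- truth
  out
}

#' Planted-parameter summary of a generated corpus
#'
#' Returns the generator's bookkeeping — true relevance counts, duplicate /
#' missing-metadata / non-English counts, the retained count and the planted
#' neighbour terms — for comparison with what the pipeline estimates.
#'
#' @param corpus a corpus produced by [generate_corpus()].
#' @return the ground-truth list.
#' @export
ground_truth_report <- function(corpus) {
  gt <- attr(corpus, "ground_truth")
  if (is.null(gt)) {
    stop("corpus carries no ground truth (not produced by generate_corpus)",
         call. = FALSE)
  }
  gt
}
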
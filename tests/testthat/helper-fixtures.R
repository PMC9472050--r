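# Shared fixtures and independent oracles.

# Per-degree counts of the published colonoscopy evaluation: total degree,
# number of videos at that degree, number of those coded relevant. These are
# printed inputs, used to reproduce the cumulative curve.
table4_counts <- function() {
  data.frame(
    degree = c(44, 41, 26, 23, 22, 21, 20, 19, 18, 17, 16, 15, 14, 13, 12,
               11, 10, 9, 7, 6, 5, 4, 3, 2, 1, 0),
    n = c(1, 1, 1, 1, 1, 1, 2, 1, 1, 2, 1, 2, 1, 1, 2,
          2, 1, 1, 2, 1, 2, 2, 2, 5, 5, 71),
    rel = c(1, 1, 1, 1, 1, 1, 2, 1, 1, 2, 1, 2, 1, 1, 2,
            2, 1, 1, 1, 1, 0, 2, 1, 1, 1, 7)
  )
}

# expand per-degree counts into one degree record per video plus a named
# relevance vector (ids are synthetic; only degree/relevance matter)
degree_records_from_counts <- function(counts) {
  ids <- character(); deg <- integer(); rel <- logical()
  for (i in seq_len(nrow(counts))) {
    n <- counts$n[i]; r <- counts$rel[i]
    id <- sprintf("d%d_v%02d", counts$degree[i], seq_len(n))
    ids <- c(ids, id)
    deg <- c(deg, rep(counts$degree[i], n))
    rel <- c(rel, rep(c(TRUE, FALSE), c(r, n - r)))
  }
  list(records = data.frame(video_id = ids, indegree = deg,
                            outdegree = 0L, total_degree = deg,
                            stringsAsFactors = FALSE),
       relevance = stats::setNames(rel, ids))
}

# Published per-term coded-sample counts (term, coded, relevant, mentioning)
table2_rows <- function() {
  data.frame(
    term = c("suprep", "peg", "sutab", "plenvu", "glycol", "miralax"),
    n_coded = 25L,
    n_relevant = c(18L, 1L, 4L, 23L, 0L, 5L),
    n_mentioning = c(9L, 0L, 4L, 15L, 0L, 2L),
    stringsAsFactors = FALSE
  )
}

# Build a coded corpus realising given per-term counts: relevant videos that
# mention the focal term get it in the title, the rest do not contain it.
coded_corpus_from_rows <- function(rows, focal = "colonoscopy") {
  vids <- list()
  for (i in seq_len(nrow(rows))) {
    tm <- rows$term[i]
    n <- rows$n_coded[i]; r <- rows$n_relevant[i]; m <- rows$n_mentioning[i]
    kind <- rep(c("rel_mention", "rel_omit", "irrel"), c(m, r - m, n - r))
    for (j in seq_len(n)) {
      title <- switch(kind[j],
        rel_mention = paste("My", focal, "with", tm),
        rel_omit = paste(tm, "bowel prep instructions"),
        irrel = paste(tm, "unboxing vlog"))
      vids[[length(vids) + 1]] <- video_records(
        sprintf("v_%s_%02d", tm, j), title = title,
        description = "some description text",
        set_label = paste0("neighbor:", tm),
        relevance = if (kind[j] == "irrel") "irrelevant" else "relevant")
    }
  }
  vids[[length(vids) + 1]] <- video_records(
    "core01", title = paste(focal, "explained"), set_label = "core")
  corpus(do.call(rbind, vids), focal_term = focal)
}

# Published batch summary inputs: new nondup relevant (A), videos with
# degree >= 1 (B), relevant among those (A∩B), per focal term.
table5_rows <- function() {
  data.frame(
    focal_term = c("colonoscopy", "fobt", "mammogram", "pap test"),
    A = c(37L, 50L, 77L, 87L),
    B = c(42L, 33L, 28L, 65L),
    AB = c(30L, 27L, 23L, 59L),
    n_retained = c(113L, 100L, 200L, 200L),
    stringsAsFactors = FALSE
  )
}

# display rounding used by the published tables (half-up, not half-even)
rhu <- function(x, digits = 0) floor(x * 10^digits + 0.5) / 10^digits

# --- independent oracles ----------------------------------------------------

# brute-force nearest-neighbour ranking: all-pairs cosine via the scalar
# cosine(), ranked with the same tie rule
oracle_neighbors <- function(vectors, focal, k) {
  others <- setdiff(rownames(vectors), focal)
  sims <- vapply(others, function(t) cosine(vectors[focal, ], vectors[t, ]),
                 numeric(1))
  ord <- order(-sims, others, method = "radix")
  data.frame(term = others[ord][seq_len(k)],
             similarity = unname(sims[ord][seq_len(k)]),
             rank = seq_len(k), stringsAsFactors = FALSE)
}

# brute-force complete-linkage agglomeration over explicit member sets,
# recomputing every inter-cluster max from the original matrix at each step
oracle_complete_linkage_heights <- function(dm) {
  clusters <- lapply(seq_len(nrow(dm)), identity)
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (j <= i) next
      h <- max(dm[clusters[[i]], clusters[[j]]])
      if (h < best[1]) best <- c(h, i, j)
    }
    heights <- c(heights, best[1])
    clusters[[best[2]]] <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters[[best[3]]] <- NULL
  }
  heights
}

# random small corpus for quick I/O and property tests
tiny_corpus <- function(seed = 1) {
  generate_corpus(
    generator_config(n_core = 20, n_expansion_per_term = 6,
                     planted_neighbor_terms = c("suprep", "miralax"),
                     background_vocab_size = 30),
    seed = seed)
}
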
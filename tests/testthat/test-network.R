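test_that("exclusion_filter applies reasons with the documented priority", {
  core <- video_records(sprintf("c%02d", 1:10), title = "colonoscopy",
                        set_label = "core")
  expn <- rbind(
    video_records("n1", language = "es", set_label = "neighbor:peg",
                  relevance = "relevant"),
    video_records("c01", set_label = "neighbor:peg", relevance = "relevant"),
    video_records("n2", set_label = "neighbor:peg", relevance = "irrelevant",
                  exclusion = "missing_metadata"),
    video_records(c("n3", "n4"), set_label = "neighbor:peg",
                  relevance = "relevant"),
    video_records("n5", language = "und", set_label = "neighbor:peg",
                  relevance = "irrelevant")
  )
  corp <- dedupe_against_core(corpus(rbind(core, expn), focal_term = "colonoscopy"))
  flt <- exclusion_filter(corp)
  expect_setequal(flt$retained, c("n3", "n4", "n5"))  # "und" trusted by default
  expect_equal(flt$tally[["non_english"]], 1)
  expect_equal(flt$tally[["duplicate_of_core"]], 1)
  expect_equal(flt$tally[["missing_metadata"]], 1)

  flt2 <- exclusion_filter(corp, treat_und_as_non_english = TRUE)
  expect_setequal(flt2$retained, c("n3", "n4"))
  expect_equal(flt2$tally[["non_english"]], 2)

  # no exclusions is the identity; all excluded warns but does not error
  clean <- corpus(rbind(core, video_records("m1", set_label = "neighbor:peg",
                                            relevance = "relevant")),
                  focal_term = "x")
  expect_equal(exclusion_filter(clean)$retained, "m1")
  allx <- corpus(rbind(core, video_records("m1", language = "fr",
                                           set_label = "neighbor:peg",
                                           relevance = "irrelevant")),
                 focal_term = "x")
  expect_warning(flt3 <- exclusion_filter(allx), "retained no videos")
  expect_length(flt3$retained, 0)
})

test_that("degree_metrics counts distinct directed core-new edges", {
  edges <- data.frame(
    source_id = c("core1", "new1", "new1", "core2", "ext", "core1"),
    target_id = c("new1", "core2", "core2", "core1", "new2", "ext"))
  rec <- degree_metrics(edges, core_ids = c("core1", "core2"),
                        new_ids = c("new1", "new2"))
  r1 <- rec[rec$video_id == "new1", ]
  expect_equal(c(r1$indegree, r1$outdegree, r1$total_degree), c(1, 1, 2))
  r2 <- rec[rec$video_id == "new2", ]          # only touched by external id
  expect_equal(r2$total_degree, 0)
  expect_equal(rec$total_degree, rec$indegree + rec$outdegree)

  expect_error(degree_metrics(edges, c("a", "b"), c("b", "c")), "overlap")
  none <- degree_metrics(edges[0, ], c("core1"), c("new1"))
  expect_equal(none$total_degree, 0)
})

test_that("threshold_curve matches a direct enumeration oracle on a toy input", {
  # degrees {2: 1 video (1 rel), 1: 2 videos (1 rel), 0: 2 videos (0 rel)}
  records <- data.frame(video_id = c("a", "b", "c", "d", "e"),
                        indegree = c(2, 1, 1, 0, 0), outdegree = 0,
                        total_degree = c(2, 1, 1, 0, 0))
  rel <- c(a = TRUE, b = TRUE, c = FALSE, d = FALSE, e = FALSE)
  curve <- threshold_curve(records, rel)
  at1 <- precision_at(curve, 1)
  expect_equal(at1$n, 3)
  expect_equal(at1$n_relevant, 2)
  expect_equal(round(at1$precision, 1), 66.7)
  expect_equal(at1$recall, 100)
  expect_equal(round(at1$f1, 1), 80.0)
  # single-degree, all-relevant corner
  all_rel <- threshold_curve(
    data.frame(video_id = letters[1:10], indegree = 0, outdegree = 0,
               total_degree = 0),
    stats::setNames(rep(TRUE, 10), letters[1:10]))
  expect_equal(nrow(all_rel), 1)
  expect_equal(c(all_rel$cum_precision, all_rel$cum_recall, all_rel$cum_f1),
               c(100, 100, 100))
  expect_error(threshold_curve(records, rel & FALSE), "zero relevant")
  expect_error(threshold_curve(records, rel[1:2]), "no relevance code")
})

test_that("curve invariants hold on random record sets", {
  set.seed(77)
  for (rep in 1:5) {
    n <- 40
    ids <- sprintf("v%02d", 1:n)
    deg <- rpois(n, 2)
    rel <- stats::setNames(runif(n) < 0.4, ids)
    if (!any(rel)) rel[1] <- TRUE
    records <- data.frame(video_id = ids, indegree = deg, outdegree = 0,
                          total_degree = deg)
    curve <- threshold_curve(records, rel)
    expect_false(is.unsorted(curve$cum_videos))
    expect_false(is.unsorted(curve$cum_recall))
    expect_equal(sum(curve$n_relevant), attr(curve, "total_relevant"))
    expect_equal(curve$cum_recall[nrow(curve)], 100)
    expect_true(all(curve$cum_precision >= 0 & curve$cum_precision <= 100))
    expect_true(all(
      curve$cum_f1 >= pmin(curve$cum_precision, curve$cum_recall) - 1e-9 &
      curve$cum_f1 <= pmax(curve$cum_precision, curve$cum_recall) + 1e-9))
    # loosest threshold: precision equals the base relevance rate
    expect_equal(curve$cum_precision[nrow(curve)], 100 * mean(rel))
    # invariant to record ordering
    perm <- sample(n)
    curve2 <- threshold_curve(records[perm, ], rel)
    expect_equal(curve2, curve)
  }
})

test_that("precision_at resolves unobserved thresholds upward and errors past the max", {
  fix <- degree_records_from_counts(table4_counts())
  curve <- threshold_curve(fix$records, fix$relevance)
  # degree 8 is unobserved; the smallest observed degree >= 8 is 9
  at8 <- precision_at(curve, 8)
  expect_equal(at8$n, 23)
  expect_equal(at8$precision, 100)
  at0 <- precision_at(curve, 0)
  expect_equal(at0$n, 113)
  expect_equal(at0$recall, 100)
  expect_error(precision_at(curve, 100), "exceeds")
})

test_that("degree filtering lifts precision on edge-informative corpora", {
  # p_edge_rel >> p_edge_irr: precision at degree >= 1 must beat the base
  # rate in at least 9 of 10 seeded replicates
  wins <- 0L
  for (s in 1:10) {
    corp <- generate_corpus(
      generator_config(n_core = 50, n_expansion_per_term = 20,
                       planted_neighbor_terms = c("suprep", "peg", "sutab"),
                       p_edge_rel = 0.1, p_edge_irr = 0.005),
      seed = 100 + s)
    ev <- evaluate_network(corp, min_degree = 1)
    base <- precision_at(ev$curve, 0)$precision
    if (ev$at$precision > base) wins <- wins + 1L
  }
  expect_gte(wins, 9)
})
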
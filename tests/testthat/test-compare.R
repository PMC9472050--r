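test_that("build_dfm counts tokens; grouping sums member rows", {
  docs <- list(d1 = c("a", "b"), d2 = "a")
  m <- build_dfm(docs)
  expect_equal(m, matrix(c(1L, 1L, 1L, 0L), nrow = 2, byrow = TRUE,
                         dimnames = list(c("d1", "d2"), c("a", "b"))))
  g <- build_dfm(docs, groups = c("g", "g"))
  expect_equal(g["g", ], c(a = 2L, b = 1L))

  set.seed(31)
  docs20 <- lapply(1:20, function(i) sample(letters[1:6], 8, replace = TRUE))
  names(docs20) <- sprintf("d%02d", 1:20)
  groups <- sample(c("x", "y", "z"), 20, replace = TRUE)
  per_doc <- build_dfm(docs20)
  grouped <- build_dfm(docs20, groups = groups)
  for (lab in unique(groups)) {
    expect_equal(grouped[lab, ],
                 colSums(per_doc[groups == lab, , drop = FALSE]))
  }
})

test_that("set_distance is Euclidean and satisfies metric axioms", {
  m <- rbind(p = c(1, 2), q = c(4, 6))
  d <- set_distance(m)
  expect_equal(d["p", "q"], 5)          # 3-4-5 triangle
  expect_equal(diag(d), c(p = 0, q = 0))
  expect_error(set_distance(m[1, , drop = FALSE]), "2 groups")

  # identical rows are at distance zero
  expect_equal(set_distance(rbind(a = c(2, 3), b = c(2, 3)))["a", "b"], 0)

  set.seed(7)
  for (rep in 1:5) {
    mm <- matrix(rpois(5 * 8, 4), nrow = 5,
                 dimnames = list(letters[1:5], NULL))
    dd <- set_distance(mm)
    expect_equal(dd, t(dd))
    expect_true(all(dd >= 0))
    for (i in 1:5) for (j in 1:5) for (k in 1:5) {
      expect_lte(dd[i, j], dd[i, k] + dd[k, j] + 1e-9)
    }
  }
})

test_that("set_distance_avg averages cross-set document pairs", {
  m <- rbind(d1 = c(0, 0), d2 = c(3, 0), d3 = c(0, 4))
  out <- set_distance_avg(m, groups = c("g1", "g1", "g2"))
  expect_equal(out["g1", "g2"], (4 + 5) / 2)
  expect_equal(out["g1", "g1"], 3)
})

test_that("keyness matches the Yates chi-square oracle and flips sign on swap", {
  # textbook 2x2 with Yates correction as independent oracle
  dfm <- rbind(tgt = c(term = 10, other = 90),
               ref = c(term = 2, other = 98))
  out <- keyness(dfm, "tgt", "ref")
  row <- out[out$term == "term", ]
  oracle <- suppressWarnings(
    stats::chisq.test(matrix(c(10, 90, 2, 98), nrow = 2, byrow = TRUE),
                      correct = TRUE))
  expect_equal(row$chi2, unname(oracle$statistic), tolerance = 1e-12)
  expect_equal(row$direction, "target")
  expect_equal(unlist(row[c("a", "b", "c", "d")], use.names = FALSE),
               c(10, 90, 2, 98))

  swapped <- keyness(dfm, "ref", "tgt")
  srow <- swapped[swapped$term == "term", ]
  expect_equal(srow$chi2, row$chi2)
  expect_equal(srow$signed_chi2, -row$signed_chi2)

  # proportionally equal rates are independent: chi2 = 0
  eq <- rbind(a = c(x = 5, y = 45), b = c(x = 10, y = 90))
  expect_equal(keyness(eq, "a", "b")$chi2, c(0, 0))
  expect_error(keyness(rbind(a = c(0, 0), b = c(1, 2)), "a", "b"),
               "zero tokens")
})

test_that("keyness on random tables equals chisq.test across many cells", {
  set.seed(19)
  dfm <- rbind(t = rpois(30, 6) + 1, r = rpois(30, 6) + 1)
  colnames(dfm) <- sprintf("w%02d", 1:30)
  out <- keyness(dfm, "t", "r")
  expect_false(is.unsorted(rev(out$chi2)))   # sorted descending
  for (i in sample(nrow(out), 8)) {
    row <- out[i, ]
    tab <- matrix(c(row$a, row$b, row$c, row$d), nrow = 2, byrow = TRUE)
    oracle <- suppressWarnings(stats::chisq.test(tab, correct = TRUE))
    expect_equal(row$chi2, unname(oracle$statistic), tolerance = 1e-9)
  }
})

test_that("planted set-specific terms key toward their set", {
  corp <- generate_corpus(generator_config(), seed = 5)
  docs <- build_token_docs(corp)
  groups <- ifelse(attr(docs, "set_label") == "core", "core", "expansion")
  dfm <- build_dfm(docs, groups = groups)
  out <- keyness(dfm, "expansion", "core")
  # background tokens live only in expansion sets
  bg <- grep("^bg", out$term)
  expect_true(all(out$direction[bg] == "target"))
  # the focal term is core-keyed
  expect_equal(out$direction[out$term == corp$focal_term], "reference")
})

test_that("hcluster_complete reproduces hand agglomeration and the oracle", {
  dm <- matrix(c(0, 1, 5,
                 1, 0, 6,
                 5, 6, 0), nrow = 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  hc <- hcluster_complete(dm)
  expect_s3_class(hc, "hclust")
  expect_equal(hc$height, c(1, 6))   # (A,B) at 1, then C at max(5,6)
  expect_equal(hc$merge[1, ], c(-1L, -2L))

  expect_error(hcluster_complete(matrix(c(0, 1, 2, 0), 2)), "symmetric")
  # n = 2 degenerates to a single merge at the pair distance
  d2 <- matrix(c(0, 3, 3, 0), 2, dimnames = list(c("x", "y"), c("x", "y")))
  expect_equal(hcluster_complete(d2)$height, 3)

  set.seed(23)
  for (n in c(4, 6, 8)) {
    x <- matrix(rnorm(n * 3), nrow = n)
    rownames(x) <- sprintf("s%d", seq_len(n))
    dm <- as.matrix(dist(x))
    hc <- hcluster_complete(dm)
    expect_false(is.unsorted(hc$height))
    expect_equal(hc$height, oracle_complete_linkage_heights(dm),
                 tolerance = 1e-9)
    # stats::hclust as a second, independent route
    ref <- stats::hclust(dist(x), method = "complete")
    expect_equal(hc$height, ref$height, tolerance = 1e-9)
    expect_equal(stats::cophenetic(hc), stats::cophenetic(ref),
                 tolerance = 1e-9)
  }
})

test_that("tied merge heights resolve to lexicographically smallest labels", {
  dm <- matrix(2, 4, 4, dimnames = list(c("d", "c", "b", "a"),
                                        c("d", "c", "b", "a")))
  diag(dm) <- 0
  hc <- hcluster_complete(dm)
  first <- sort(hc$labels[-hc$merge[1, ]])
  expect_equal(first, c("a", "b"))
})

test_that("dendrograms serialise to Newick", {
  corp <- tiny_corpus(seed = 12)
  docs <- build_token_docs(corp)
  dfm <- build_dfm(docs, groups = attr(docs, "set_label"))
  hc <- hcluster_complete(set_distance(dfm))
  f <- withr::local_tempfile(fileext = ".nwk")
  write_newick(hc, f)
  tree <- ape::read.tree(f)
  expect_setequal(tree$tip.label, gsub(":", "-", rownames(dfm)))
})
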
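test_that("cosine matches hand values and rejects degenerate input", {
  expect_equal(cosine(c(3, 4), c(3, 4)), 1.0)
  expect_equal(cosine(c(1, 0), c(0, 1)), 0.0)
  expect_equal(cosine(c(1, 1), c(1, 0)), 1 / sqrt(2), tolerance = 1e-12)
  expect_equal(cosine(c(1, 2), c(-1, -2)), -1.0)
  expect_equal(cosine(c(1, 1), c(1, 0)), cosine(c(1, 0), c(1, 1)))
  expect_error(cosine(c(0, 0), c(1, 0)), "zero vector")
  expect_error(cosine(c(1, 0, 0), c(1, 0)), "length")
})

test_that("nearest_neighbors agrees with the brute-force cosine oracle", {
  set.seed(42)
  for (V in c(8, 60, 200)) {
    vecs <- matrix(rnorm(V * 10), nrow = V,
                   dimnames = list(sprintf("t%03d", seq_len(V)), NULL))
    model <- structure(list(vectors = vecs), class = "embedding_model")
    k <- min(V - 1, 7)
    got <- nearest_neighbors(model, "t001", k)
    want <- oracle_neighbors(vecs, "t001", k)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("neighbor ranking is invariant to global positive scaling and breaks ties by term", {
  vecs <- matrix(c(1, 0,  0.9, 0.1,  0, 1), nrow = 3, byrow = TRUE,
                 dimnames = list(c("a", "b", "c"), NULL))
  model <- structure(list(vectors = vecs), class = "embedding_model")
  expect_equal(nearest_neighbors(model, "a", 1)$term, "b")
  scaled <- structure(list(vectors = vecs * 37), class = "embedding_model")
  expect_equal(nearest_neighbors(scaled, "a", 2)$term,
               nearest_neighbors(model, "a", 2)$term)
  # identical vectors tie; lexicographically smaller term first
  tied <- matrix(c(1, 0,  0, 1,  0, 1), nrow = 3, byrow = TRUE,
                 dimnames = list(c("f", "zed", "abc"), NULL))
  tm <- structure(list(vectors = tied), class = "embedding_model")
  expect_equal(nearest_neighbors(tm, "f", 2)$term, c("abc", "zed"))
  # k larger than vocab returns everything, ranks consecutive
  expect_equal(nearest_neighbors(tm, "f", 99)$rank, 1:2)
  expect_error(nearest_neighbors(tm, "missing", 1), "missing")
})

test_that("training is deterministic, respects dim and min_count", {
  docs <- tiny_docs <- build_token_docs(tiny_corpus(seed = 2))
  m1 <- train_embeddings(docs, dim = 16, min_count = 3, epochs = 2, seed = 7)
  m2 <- train_embeddings(docs, dim = 16, min_count = 3, epochs = 2, seed = 7)
  expect_identical(m1$vectors, m2$vectors)
  m3 <- train_embeddings(docs, dim = 16, min_count = 3, epochs = 2, seed = 8)
  expect_false(identical(m1$vectors, m3$vectors))
  expect_equal(ncol(m1$vectors), 16)
  expect_true(all(is.finite(m1$vectors)))
  # a token occurring min_count - 1 times is absent from the vocabulary
  toy <- list(rep("common", 10), c("common", "rare", "common", "rare"),
              c("common", "other", "other", "other"))
  mt <- train_embeddings(toy, dim = 4, min_count = 3, epochs = 1, seed = 1)
  expect_false("rare" %in% rownames(mt$vectors))
  expect_true(all(c("common", "other") %in% rownames(mt$vectors)))
  expect_error(train_embeddings(list(), dim = 4), "at least one document")
  expect_error(train_embeddings(toy, dim = 1), "dim")
  expect_warning(train_embeddings(toy, dim = 4, min_count = 3,
                                  focal_term = "rare"), "rare")
})

test_that("both algorithms run and expose their params", {
  docs <- build_token_docs(tiny_corpus(seed = 4))
  for (alg in c("skipgram", "cbow")) {
    m <- train_embeddings(docs, dim = 8, epochs = 1, min_count = 2,
                          algorithm = alg, seed = 3)
    expect_equal(m$params$algorithm, alg)
    expect_true(all(is.finite(m$vectors)))
  }
})

test_that("embedding models persist in word2vec text format", {
  docs <- build_token_docs(tiny_corpus(seed = 6))
  m <- train_embeddings(docs, dim = 8, epochs = 1, min_count = 2, seed = 5)
  f <- withr::local_tempfile(fileext = ".txt")
  write_embeddings(m, f)
  hdr <- strsplit(readLines(f, n = 1), " ")[[1]]
  expect_equal(as.integer(hdr), c(nrow(m$vectors), 8L))
  back <- read_embeddings(f)
  expect_equal(rownames(back$vectors), rownames(m$vectors))
  expect_equal(unname(back$vectors), unname(m$vectors), tolerance = 1e-7)
})

test_that("planted neighbour terms achieve median rank <= k across 10 seeds", {
  # end-to-end neighbour recovery on the default synthetic world; pooled
  # ranks of all planted terms over 10 seeded replicates
  terms <- c("suprep", "peg", "sutab", "plenvu", "glycol", "miralax")
  ranks <- unlist(lapply(1:10, function(s) {
    corp <- generate_corpus(generator_config(), seed = s)
    docs <- build_token_docs(corp)
    model <- train_embeddings(docs, seed = s, focal_term = corp$focal_term)
    nb <- nearest_neighbors(model, corp$focal_term,
                            k = nrow(model$vectors) - 1)
    match(terms, nb$term)
  }))
  expect_true(all(is.finite(ranks)))
  expect_lte(median(ranks), 6)
})
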
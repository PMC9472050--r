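#' Train word embeddings on token documents
#'
#' Learns dense term vectors from token co-occurrence with a word2vec-style
#' neural model: CBOW (default) or skip-gram, trained with negative sampling
#' and a linearly decaying learning rate. Training is single-threaded and
#' uses an internal PRNG, so a given `(docs, params, seed)` triple always
#' yields bit-identical vectors.
#'
#' Tokens occurring fewer than `min_count` times across the corpus are
#' dropped from the vocabulary before training (the word2vec convention);
#' remaining documents shrink accordingly but are not re-windowed.
#'
#' @param docs a `token_docs` object (or plain list of token vectors).
#' @param dim vector dimensionality (>= 2). Default 50.
#' @param window maximum context window; the effective window per target is
#'   drawn uniformly from 1..window. Default 5.
#' @param epochs training passes over the corpus. Default 5.
#' @param min_count minimum corpus frequency for a token to enter the
#'   vocabulary. Default 5.
#' @param algorithm `"skipgram"` (default; the more reliable choice on
#'   corpora of this size) or `"cbow"`.
#' @param negative negative samples per positive example. Default 5.
#' @param sample frequent-word subsampling threshold (word2vec's `sample`);
#'   occurrences of a token with corpus share f are kept with probability
#'   `sqrt(sample/f) + sample/f`. Default `1e-3`; `0` disables.
#' @param alpha initial learning rate.
#' @param seed integer seed for the internal PRNG.
#' @param focal_term optional; warn if this token is absent from (or rare in)
#'   the vocabulary, since downstream neighbour ranking needs it.
#' @return an object of class `"embedding_model"`: list with `vectors` (the
#'   input vectors, a vocab x dim numeric matrix, rownames are tokens,
#'   ordered by corpus frequency; these drive all similarity queries),
#'   `context` (the output/context vectors, same shape), `counts`, and
#'   `params`.
#' @export
train_embeddings <- function(docs, dim = 50L, window = 5L, epochs = 5L,
                             min_count = 5L, algorithm = c("skipgram", "cbow"),
                             negative = 5L, sample = 1e-3, alpha = 0.025,
                             seed = 1L, focal_term = NULL) {
  algorithm <- match.arg(algorithm)
  if (dim < 2) stop("embedding dim must be >= 2", call. = FALSE)
  if (min_count < 1) stop("min_count must be >= 1", call. = FALSE)
  docs <- unclass(docs)
  if (!length(docs) || !any(lengths(docs) >= 2)) {
    stop("need at least one document with >= 2 tokens", call. = FALSE)
  }
  tab <- table(unlist(docs, use.names = FALSE))
  tab <- tab[tab >= min_count]
  if (!length(tab)) {
    stop("no token reaches min_count = ", min_count, call. = FALSE)
  }
  # frequency-descending, token-ascending: a deterministic vocabulary order
  ord <- order(-as.integer(tab), names(tab), method = "radix")
  counts <- as.numeric(tab)[ord]
  vocab <- names(tab)[ord]
  if (!is.null(focal_term) && !(focal_term %in% vocab)) {
    warning("focal term \"", focal_term, "\" is below min_count or absent; ",
            "nearest_neighbors() will fail for it", call. = FALSE)
  }
  idx <- lapply(docs, function(d) {
    m <- match(d, vocab)
    as.integer(m[!is.na(m)])
  })
  idx <- idx[lengths(idx) > 0]
  vectors <- w2v_train(idx, counts, as.integer(dim), as.integer(window),
                       as.integer(epochs), as.integer(negative),
                       as.numeric(alpha),
                       if (algorithm == "cbow") 0L else 1L,
                       as.numeric(sample), as.numeric(seed))
  context <- attr(vectors, "context")
  attr(vectors, "context") <- NULL
  rownames(vectors) <- vocab
  rownames(context) <- vocab
  structure(
    list(vectors = vectors, context = context,
         counts = stats::setNames(counts, vocab),
         params = list(dim = as.integer(dim), window = as.integer(window),
                       epochs = as.integer(epochs),
                       min_count = as.integer(min_count),
                       algorithm = algorithm, negative = as.integer(negative),
                       sample = sample, alpha = alpha,
                       seed = as.integer(seed))),
    class = "embedding_model"
  )
}

#' @export
print.embedding_model <- function(x, ...) {
  cat(sprintf("<embedding_model> %d terms x %d dims (%s, window %d, %d epochs, seed %d)\n",
              nrow(x$vectors), ncol(x$vectors), x$params$algorithm,
              x$params$window, x$params$epochs, x$params$seed))
  invisible(x)
}

#' Cosine similarity between two vectors
#'
#' @param u,v numeric vectors of equal length; both must be nonzero.
#' @return a number in \[-1, 1\].
#' @export
cosine <- function(u, v) {
  if (length(u) != length(v)) stop("vectors differ in length", call. = FALSE)
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) {
    stop("cosine similarity is undefined for a zero vector", call. = FALSE)
  }
  min(1, max(-1, sum(u * v) / (nu * nv)))
}

#' Nearest-neighbour terms of a focal token
#'
#' Ranks every other vocabulary term by cosine similarity to the focal
#' term's vector, descending; ties broken lexicographically by term so
#' output is stable. The focal term itself is excluded.
#'
#' @param model an `embedding_model`.
#' @param focal token to expand around; must be in the vocabulary.
#' @param k how many neighbours to return (capped at vocab size - 1).
#' @return data.frame with columns `term`, `similarity`, `rank`.
#' @export
nearest_neighbors <- function(model, focal, k = 6L) {
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  V <- model$vectors
  if (!(focal %in% rownames(V))) {
    stop("focal term \"", focal, "\" is not in the embedding vocabulary",
         call. = FALSE)
  }
  f <- V[focal, ]
  others <- rownames(V)[rownames(V) != focal]
  norms <- sqrt(rowSums(V[others, , drop = FALSE]^2))
  if (any(norms == 0)) {
    stop("zero vector in vocabulary: ",
         paste(others[norms == 0], collapse = ", "), call. = FALSE)
  }
  sims <- as.numeric(V[others, , drop = FALSE] %*% f) / (norms * sqrt(sum(f^2)))
  sims <- pmin(1, pmax(-1, sims))
  ord <- order(-sims, others, method = "radix")
  k <- min(as.integer(k), length(others))
  sel <- ord[seq_len(k)]
  data.frame(term = others[sel], similarity = sims[sel], rank = seq_len(k),
             stringsAsFactors = FALSE)
}

#' Persist or load an embedding model (word2vec text format)
#'
#' Header line `"<vocab size> <dim>"`, then one line per token with its
#' vector, space-separated — compatible with other word2vec tooling.
#' Frequencies and hyperparameters are not stored in this format; a model
#' read back carries only vocabulary and vectors.
#'
#' @param model an `embedding_model`.
#' @param path destination / source file.
#' @return `path` (write) or an `embedding_model` (read).
#' @export
write_embeddings <- function(model, path) {
  V <- model$vectors
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(sprintf("%d %d", nrow(V), ncol(V)), con)
  for (i in seq_len(nrow(V))) {
    writeLines(paste(rownames(V)[i],
                     paste(sprintf("%.9g", V[i, ]), collapse = " ")), con)
  }
  invisible(path)
}

#' @rdname write_embeddings
#' @export
read_embeddings <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]])
  if (length(hdr) != 2 || any(is.na(hdr))) {
    stop("bad embedding file header: ", lines[1], call. = FALSE)
  }
  n <- hdr[1]; d <- hdr[2]
  body <- strsplit(lines[1 + seq_len(n)], " ", fixed = TRUE)
  vocab <- vapply(body, `[[`, "", 1L)
  vecs <- t(vapply(body, function(p) as.numeric(p[-1]), numeric(d)))
  rownames(vecs) <- vocab
  structure(list(vectors = vecs, counts = NULL,
                 params = list(dim = d, source = path)),
            class = "embedding_model")
}
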
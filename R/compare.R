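#' Document-feature matrix
#'
#' Token counts per document (rows) over the corpus vocabulary (columns,
#' sorted lexicographically so column order is deterministic). With
#' `groups`, rows are summed within each group label — the representation
#' used for set-level distances and keyness.
#'
#' @param docs a `token_docs` object or plain list of token vectors.
#' @param groups optional character vector of group labels, one per
#'   document (e.g. the corpus `set_label`s); `NULL` keeps one row per doc.
#' @return an integer matrix with dimnames; rows are docs or groups.
#' @export
build_dfm <- function(docs, groups = NULL) {
  docs <- unclass(docs)
  if (!length(docs)) stop("no documents", call. = FALSE)
  vocab <- sort(unique(unlist(docs, use.names = FALSE)), method = "radix")
  m <- matrix(0L, nrow = length(docs), ncol = length(vocab),
              dimnames = list(names(docs), vocab))
  for (i in seq_along(docs)) {
    if (!length(docs[[i]])) next
    tb <- table(docs[[i]])
    m[i, names(tb)] <- as.integer(tb)
  }
  if (!is.null(groups)) {
    if (length(groups) != length(docs)) {
      stop("groups must have one label per document", call. = FALSE)
    }
    g <- sort(unique(groups), method = "radix")
    gm <- matrix(0L, nrow = length(g), ncol = ncol(m),
                 dimnames = list(g, vocab))
    for (lab in g) {
      gm[lab, ] <- as.integer(colSums(m[groups == lab, , drop = FALSE]))
    }
    m <- gm
  }
  m
}

#' Euclidean distance between video-set feature vectors
#'
#' Operates on a grouped document-feature matrix: each set is its summed
#' count vector, and the pairwise Euclidean distances form a symmetric
#' matrix with zero diagonal. Raw counts (no weighting) are the default
#' representation throughout the package; pass an averaged or weighted
#' matrix if another convention is wanted.
#'
#' @param dfm a grouped DFM from [build_dfm()] with >= 2 rows.
#' @return a symmetric numeric matrix of distances over the set labels.
#' @export
set_distance <- function(dfm) {
  if (nrow(dfm) < 2) stop("need at least 2 groups", call. = FALSE)
  as.matrix(stats::dist(dfm, method = "euclidean"))
}

#' Average pairwise document distance between sets
#'
#' The alternative reading of a set-level distance: the mean Euclidean
#' distance over all cross-set document pairs (and, on the diagonal, over
#' within-set pairs). Heavier than [set_distance()] and kept for
#' sensitivity checks.
#'
#' @param dfm an ungrouped (per-document) DFM.
#' @param groups group label per row of `dfm`.
#' @return symmetric matrix of mean pairwise distances.
#' @export
set_distance_avg <- function(dfm, groups) {
  if (length(groups) != nrow(dfm)) stop("groups must match dfm rows", call. = FALSE)
  g <- sort(unique(groups), method = "radix")
  dd <- as.matrix(stats::dist(dfm))
  out <- matrix(0, length(g), length(g), dimnames = list(g, g))
  for (i in seq_along(g)) for (j in seq_along(g)) {
    block <- dd[groups == g[i], groups == g[j], drop = FALSE]
    if (i == j) {
      n <- nrow(block)
      out[i, j] <- if (n < 2) 0 else sum(block) / (n * (n - 1))
    } else {
      out[i, j] <- mean(block)
    }
  }
  out
}

#' Keyness: chi-square contrast of term frequencies between two sets
#'
#' For every term, forms the 2x2 table (term count vs. count of all other
#' tokens, target set vs. reference set) and computes the Yates
#' continuity-corrected chi-square. `direction` records whether the term is
#' over-represented in the target or the reference set; `signed_chi2`
#' carries the same statistic negated for reference-leaning terms, which is
#' the usual keyness plot axis.
#'
#' @param dfm a grouped DFM containing both labels.
#' @param target,reference row labels of `dfm`.
#' @return data.frame of class `"keyness"`, sorted by `chi2` descending
#'   (ties broken by term), with columns `term`, `chi2`, `signed_chi2`,
#'   `direction`, `a`, `b`, `c`, `d`.
#' @export
keyness <- function(dfm, target, reference) {
  for (lab in c(target, reference)) {
    if (!(lab %in% rownames(dfm))) stop("no such group: ", lab, call. = FALSE)
  }
  a <- as.numeric(dfm[target, ])
  c_ <- as.numeric(dfm[reference, ])
  nt <- sum(a); nr <- sum(c_)
  if (nt == 0 || nr == 0) stop("a group has zero tokens", call. = FALSE)
  b <- nt - a
  d <- nr - c_
  chi2 <- yates_chi2(a, b, c_, d)
  dir <- ifelse(a / nt >= c_ / nr, "target", "reference")
  out <- data.frame(term = colnames(dfm), chi2 = chi2,
                    signed_chi2 = ifelse(dir == "target", chi2, -chi2),
                    direction = dir, a = a, b = b, c = c_, d = d,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$chi2, out$term, method = "radix"), ]
  rownames(out) <- NULL
  class(out) <- c("keyness", "data.frame")
  out
}

# Yates-corrected 2x2 chi-square, vectorised; 0 when the correction
# exceeds |ad - bc| (the standard clamp) or a margin is empty.
yates_chi2 <- function(a, b, c_, d) {
  n <- a + b + c_ + d
  num <- pmax(abs(a * d - b * c_) - n / 2, 0)
  den <- (a + b) * (c_ + d) * (a + c_) * (b + d)
  ifelse(den == 0, 0, n * num^2 / den)
}

#' Complete-linkage hierarchical clustering
#'
#' Agglomerative clustering where the distance between two clusters is the
#' maximum pairwise distance between their members. Implemented directly so
#' tie-breaking is deterministic: among equal-height candidate merges, the
#' pair whose lexicographically smallest member labels sort first is merged.
#' Returns a standard `hclust` object, so `plot()`, `cutree()` and
#' `as.dendrogram()` work.
#'
#' @param dist_mat symmetric distance matrix (or `dist` object) with
#'   labelled rows, n >= 2.
#' @return an object of class `"hclust"` (method `"complete"`); merge
#'   heights are nondecreasing.
#' @export
hcluster_complete <- function(dist_mat) {
  dm <- as.matrix(dist_mat)
  n <- nrow(dm)
  if (n < 2) stop("need at least 2 items", call. = FALSE)
  if (!isSymmetric(unname(dm), tol = 1e-8)) {
    stop("distance matrix must be symmetric", call. = FALSE)
  }
  labels <- rownames(dm)
  if (is.null(labels)) labels <- as.character(seq_len(n))

  # active cluster bookkeeping: hclust id (-leaf or +step), min member label
  cl_id <- -seq_len(n)
  cl_min <- labels
  active <- rep(TRUE, n)
  d <- dm
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)

  for (step in seq_len(n - 1)) {
    idx <- which(active)
    best <- NULL
    for (ii in seq_along(idx)) {
      for (jj in seq_along(idx)) {
        if (jj <= ii) next
        i <- idx[ii]; j <- idx[jj]
        lab <- sort(c(cl_min[i], cl_min[j]), method = "radix")
        cand <- list(h = d[i, j], l1 = lab[1], l2 = lab[2], i = i, j = j)
        if (is.null(best) || cand$h < best$h - 1e-12 ||
            (abs(cand$h - best$h) <= 1e-12 &&
             (cand$l1 < best$l1 ||
              (cand$l1 == best$l1 && cand$l2 < best$l2)))) {
          best <- cand
        }
      }
    }
    i <- best$i; j <- best$j
    merge[step, ] <- order_merge_pair(cl_id[i], cl_id[j])
    height[step] <- best$h
    # complete linkage update: new cluster lives in slot i
    for (k in which(active)) {
      if (k == i || k == j) next
      d[i, k] <- d[k, i] <- max(d[i, k], d[j, k])
    }
    active[j] <- FALSE
    cl_id[i] <- step
    cl_min[i] <- min(cl_min[i], cl_min[j])
  }

  structure(list(merge = merge, height = height,
                 order = hclust_leaf_order(merge),
                 labels = labels, method = "complete",
                 dist.method = "euclidean",
                 call = match.call()),
            class = "hclust")
}

# hclust merge-row convention: singletons (negative) before clusters,
# singletons by leaf index, clusters by formation step
order_merge_pair <- function(a, b) {
  key <- function(x) if (x < 0) c(0, -x) else c(1, x)
  ka <- key(a); kb <- key(b)
  if (ka[1] < kb[1] || (ka[1] == kb[1] && ka[2] <= kb[2])) c(a, b) else c(b, a)
}

# leaf order for plotting: left-to-right depth-first walk of the merge tree
hclust_leaf_order <- function(merge) {
  walk <- function(node) {
    if (node < 0) return(-node)
    c(walk(merge[node, 1]), walk(merge[node, 2]))
  }
  walk(nrow(merge))
}

#' Write a dendrogram in Newick format
#'
#' Characters reserved in Newick (`:;,()` and whitespace) are replaced by
#' `-` in leaf labels, so `"neighbor:suprep"` serialises as
#' `"neighbor-suprep"`.
#'
#' @param hc an `hclust` object (e.g. from [hcluster_complete()]).
#' @param path destination file.
#' @export
write_newick <- function(hc, path) {
  hc$labels <- gsub("[:;,()[:space:]]", "-", hc$labels)
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}

#' Write a distance matrix or keyness table as CSV
#'
#' @param x a matrix from [set_distance()] or a `keyness` data.frame.
#' @param path destination.
#' @export
write_table_csv <- function(x, path) {
  if (is.matrix(x)) {
    utils::write.csv(data.frame(set = rownames(x), x, check.names = FALSE),
                     path, row.names = FALSE, quote = FALSE)
  } else {
    utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
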
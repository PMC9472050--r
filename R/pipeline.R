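#' Run manifest
#'
#' Every pipeline stage drops a JSON manifest beside its outputs: the stage
#' name, the parameter snapshot, the seed, MD5 digests of the input files,
#' the output paths and the package version. Two runs with identical
#' manifests (in deterministic mode) produce byte-identical outputs.
#'
#' @param out_dir stage output directory.
#' @param stage stage name.
#' @param params named list of parameters.
#' @param inputs character vector of input file paths (digested).
#' @param outputs character vector of output file paths.
#' @param seed the seed in force, if any.
#' @return path of the written manifest, invisibly.
#' @export
write_manifest <- function(out_dir, stage, params = list(), inputs = character(),
                           outputs = character(), seed = NULL) {
  digests <- if (length(inputs)) {
    as.list(tools::md5sum(inputs))
  } else list()
  manifest <- list(
    stage = stage,
    version = as.character(utils::packageVersion("expandnet")),
    seed = seed,
    params = params,
    input_md5 = digests,
    outputs = as.list(basename(outputs))
  )
  path <- file.path(out_dir, paste0("manifest_", stage, ".json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  invisible(path)
}

#' Pipeline stages
#'
#' Each `cmd_*` function is one stage of the retrieval-evaluation pipeline;
#' [cli_main()] exposes them as subcommands. All write their artifacts plus
#' a manifest into `out_dir` and return the main result invisibly.
#'
#' @param out_dir output directory (created if needed).
#' @param config a generator config ([generator_config()]) for `cmd_simulate`,
#'   a run config ([run_config()]) elsewhere.
#' @param seed integer seed.
#' @name pipeline
NULL

#' @rdname pipeline
#' @export
cmd_simulate <- function(out_dir, config = generator_config(), seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  corp <- generate_corpus(config, seed = seed)
  corpus_path <- file.path(out_dir, "corpus.jsonl")
  edges_path <- file.path(out_dir, "edges.tsv")
  write_corpus(corp, corpus_path, edges_path = edges_path)
  gt <- ground_truth_report(corp)
  gt$config <- unclass(gt$config)
  jsonlite::write_json(gt, file.path(out_dir, "ground_truth.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  write_manifest(out_dir, "simulate", params = unclass(config),
                 outputs = c(corpus_path, edges_path), seed = seed)
  message(sprintf("simulate: %d videos, %d edges -> %s",
                  nrow(corp$videos), nrow(corp$edges), out_dir))
  invisible(corp)
}

#' @rdname pipeline
#' @param corpus_path corpus JSONL/CSV file (from `cmd_simulate` or external).
#' @export
cmd_embed <- function(corpus_path, out_dir, config = run_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  corp <- read_corpus(corpus_path, focal_term = config$focal_term)
  docs <- build_token_docs(corp, stopwords = load_stopwords(config$stopwords))
  model <- train_embeddings(docs, dim = config$dim, window = config$window,
                            epochs = config$epochs,
                            min_count = config$min_count,
                            algorithm = config$algorithm,
                            negative = config$negative, seed = config$seed,
                            focal_term = config$focal_term)
  nb <- nearest_neighbors(model, config$focal_term, k = config$k_neighbors)
  model_path <- file.path(out_dir, "model.txt")
  nb_path <- file.path(out_dir, "neighbors.csv")
  write_embeddings(model, model_path)
  utils::write.csv(nb, nb_path, row.names = FALSE, quote = FALSE)
  write_manifest(out_dir, "embed", params = unclass(config),
                 inputs = corpus_path, outputs = c(model_path, nb_path),
                 seed = config$seed)
  message(sprintf("embed: vocab %d, top neighbour of \"%s\" is \"%s\"",
                  nrow(model$vectors), config$focal_term, nb$term[1]))
  invisible(list(model = model, neighbors = nb))
}

#' @rdname pipeline
#' @param focal focal term override; defaults to the one on the corpus file.
#' @export
cmd_recall <- function(corpus_path, out_dir, focal = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  corp <- read_corpus(corpus_path)
  if (!is.null(focal)) corp$focal_term <- focal
  report <- recall_improvement(corp)
  path <- file.path(out_dir, "recall_report.csv")
  write_recall_report(report, path)
  write_manifest(out_dir, "recall", params = list(focal = corp$focal_term),
                 inputs = corpus_path, outputs = path)
  message(sprintf("recall: %d coded, %d relevant, %d omit the focal term",
                  report$n_coded[nrow(report)], report$n_relevant[nrow(report)],
                  report$n_relevant_omitting[nrow(report)]))
  invisible(report)
}

#' @rdname pipeline
#' @export
cmd_compare <- function(corpus_path, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  corp <- read_corpus(corpus_path)
  docs <- build_token_docs(corp)
  groups <- attr(docs, "set_label")
  dfm <- build_dfm(docs, groups = groups)
  dist_path <- file.path(out_dir, "set_distances.csv")
  key_path <- file.path(out_dir, "keyness.csv")
  nwk_path <- file.path(out_dir, "dendrogram.nwk")
  dd <- set_distance(dfm)
  write_table_csv(dd, dist_path)
  # keyness of core vs. pooled expansion sets
  pooled <- rbind(core = dfm["core", ],
                  expansion = colSums(dfm[rownames(dfm) != "core", , drop = FALSE]))
  kk <- keyness(pooled, target = "core", reference = "expansion")
  write_table_csv(kk, key_path)
  hc <- hcluster_complete(dd)
  write_newick(hc, nwk_path)
  write_manifest(out_dir, "compare", inputs = corpus_path,
                 outputs = c(dist_path, key_path, nwk_path))
  message(sprintf("compare: %d sets, top core-keyed term \"%s\"",
                  nrow(dfm), kk$term[kk$direction == "target"][1]))
  invisible(list(dfm = dfm, distances = dd, keyness = kk, dendrogram = hc))
}

#' @rdname pipeline
#' @param edges_path edge list file; defaults to `edges.tsv` beside the corpus.
#' @param min_degree threshold for the summary statistics.
#' @export
cmd_network <- function(corpus_path, out_dir, edges_path = NULL,
                        min_degree = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(edges_path)) {
    edges_path <- file.path(dirname(corpus_path), "edges.tsv")
  }
  if (!file.exists(edges_path)) {
    stop("no edge list at ", edges_path,
         "; run the simulate stage (or pass edges_path)", call. = FALSE)
  }
  corp <- read_corpus(corpus_path, edges = edges_path)
  ev <- evaluate_network(corp, min_degree = min_degree)
  curve_path <- file.path(out_dir, "threshold_curve.csv")
  write_threshold_curve(ev$curve, curve_path)
  summary_path <- file.path(out_dir, "network_summary.json")
  jsonlite::write_json(list(exclusions = as.list(ev$tally),
                            min_degree = min_degree, at_threshold = ev$at),
                       summary_path, auto_unbox = TRUE, pretty = TRUE)
  write_manifest(out_dir, "network", params = list(min_degree = min_degree),
                 inputs = c(corpus_path, edges_path),
                 outputs = c(curve_path, summary_path))
  message(sprintf("network: %d retained, precision %.0f%% at degree >= %d",
                  ev$tally[["retained"]], ev$at$precision, min_degree))
  invisible(ev)
}

#' Network precision evaluation of a corpus
#'
#' The in-memory composition of the network stage: flag duplicates, apply
#' the exclusion filter, compute degree records against the core set, build
#' the cumulative threshold curve and read it at `min_degree`.
#'
#' @param corp an `expn_corpus` with relevance-coded expansion videos and edges.
#' @param min_degree threshold for the summary.
#' @return list with `records`, `curve`, `tally` and `at` (the
#'   [precision_at()] summary).
#' @export
evaluate_network <- function(corp, min_degree = 1L) {
  corp <- dedupe_against_core(corp)
  flt <- exclusion_filter(corp)
  records <- degree_metrics(corp$edges, core_ids(corp), flt$retained)
  rel <- stats::setNames(flt$videos$relevance == "relevant", flt$videos$video_id)
  curve <- threshold_curve(records, rel)
  list(records = records, curve = curve, tally = flt$tally,
       at = precision_at(curve, min_degree))
}

#' Summary retrieval statistics for one focal-term run
#'
#' One row of the batch report: the number of new, non-duplicate relevant
#' videos (set A), the videos with total degree >= `min_degree` (set B),
#' their intersection, and the resulting precision (A∩B / B) and recall
#' (A∩B / A), as integer percentages.
#'
#' @param corp an `expn_corpus`.
#' @param min_degree degree threshold (default 1, the liberal threshold).
#' @return one-row data.frame.
#' @export
summary_row <- function(corp, min_degree = 1L) {
  ev <- evaluate_network(corp, min_degree = min_degree)
  A <- attr(ev$curve, "total_relevant")
  B <- ev$at$n
  AB <- ev$at$n_relevant
  data.frame(focal_term = corp$focal_term,
             n_coded = sum(grepl("^neighbor:", corp$videos$set_label) &
                             corp$videos$relevance != "uncoded"),
             n_relevant_new = A, n_at_degree = B, n_relevant_at_degree = AB,
             precision_pct = round_half_up(100 * AB / B),
             recall_pct = round_half_up(100 * AB / A),
             stringsAsFactors = FALSE)
}

#' @rdname pipeline
#' @param corpus_paths character vector of corpus files, one per focal term
#'   (each with an `edges.tsv` beside it or a same-prefix edge file).
#' @export
cmd_report <- function(corpus_paths, out_dir, min_degree = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(corpus_paths, function(p) {
    edges_path <- file.path(dirname(p), "edges.tsv")
    corp <- read_corpus(p, edges = if (file.exists(edges_path)) edges_path)
    summary_row(corp, min_degree = min_degree)
  })
  out <- do.call(rbind, rows)
  path <- file.path(out_dir, "summary.csv")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  write_manifest(out_dir, "report", params = list(min_degree = min_degree),
                 inputs = corpus_paths, outputs = path)
  message(sprintf("report: %d focal term(s) summarised", nrow(out)))
  invisible(out)
}

#' Command-line entry point
#'
#' `cli_main(c("simulate", "--out-dir", "run1", "--seed", "7"))` etc.
#' Subcommands: `simulate`, `embed`, `recall`, `compare`, `network`,
#' `report`. Common flags: `--config` (flat key=value file), `--seed`,
#' `--out-dir`, `--corpus`, `--edges`, `--min-degree`, `--k`, `--focal`.
#' An Rscript wrapper is installed at
#' `system.file("scripts", "expandnet", package = "expandnet")`.
#'
#' @param args character vector, default `commandArgs(trailingOnly = TRUE)`.
#' @return the stage result, invisibly.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) {
    stop("usage: expandnet <simulate|embed|recall|compare|network|report> [flags]",
         call. = FALSE)
  }
  cmd <- args[[1]]
  opts <- parse_flags(args[-1])
  out_dir <- opts[["out-dir"]] %||% "."
  cfg <- if (!is.null(opts[["config"]])) read_run_config(opts[["config"]])
         else run_config()
  if (!is.null(opts[["seed"]])) cfg$seed <- as.integer(opts[["seed"]])
  if (!is.null(opts[["k"]])) cfg$k_neighbors <- as.integer(opts[["k"]])
  if (!is.null(opts[["focal"]])) cfg$focal_term <- opts[["focal"]]
  if (!is.null(opts[["min-degree"]])) cfg$min_degree <- as.integer(opts[["min-degree"]])
  corpus_path <- opts[["corpus"]]
  switch(cmd,
    simulate = cmd_simulate(out_dir, seed = cfg$seed),
    embed = cmd_embed(need(corpus_path, "--corpus"), out_dir, config = cfg),
    recall = cmd_recall(need(corpus_path, "--corpus"), out_dir,
                        focal = opts[["focal"]]),
    compare = cmd_compare(need(corpus_path, "--corpus"), out_dir),
    network = cmd_network(need(corpus_path, "--corpus"), out_dir,
                          edges_path = opts[["edges"]],
                          min_degree = cfg$min_degree),
    report = cmd_report(strsplit(need(corpus_path, "--corpus"), ",")[[1]],
                        out_dir, min_degree = cfg$min_degree),
    stop("unknown subcommand: ", cmd, call. = FALSE)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

need <- function(x, flag) {
  if (is.null(x)) stop("missing required flag ", flag, call. = FALSE)
  x
}

parse_flags <- function(args) {
  opts <- list()
  i <- 1
  while (i <= length(args)) {
    a <- args[[i]]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a, call. = FALSE)
    key <- substring(a, 3)
    if (i == length(args) || startsWith(args[[i + 1]], "--")) {
      opts[[key]] <- TRUE
      i <- i + 1
    } else {
      opts[[key]] <- args[[i + 1]]
      i <- i + 2
    }
  }
  opts
}
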
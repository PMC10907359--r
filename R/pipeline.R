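# End-to-end pipeline: generate -> keywords -> cluster -> concern -> HMM.
#
# A single master seed deterministically spawns per-stage seeds, so an
# identical configuration produces byte-identical artifacts and an identical
# manifest of file hashes.

#' Pipeline configuration
#'
#' Validates and assembles the per-stage parameter blocks of a full run. The
#' default checkpoint timeline mirrors the motivating case study: four event
#' checkpoints in chronological order (the Guizhou transfer-truck accident,
#' the "20 new rules", the Xinjiang fire, the Zhejiang people-first policy)
#' with corpus sizes equal to the pooled per-event post counts and
#' original-event concern weights of 0.73, 0.37, 0.35 and 0.29; the mass left
#' by the original-event weight is split 2:1:1 over derived event, public
#' prediction and public expectation.
#'
#' @param events List of event blocks, each a list with `name`, `n_docs` and
#'   either `dimension_weights` (length 4) or `original_weight` (scalar).
#' @param generator Named list of overrides passed to [corpus_config()]
#'   (e.g. `separation`, `doc_length_mean`).
#' @param tfidf List with `mode`, `top_k` (default 100) and `concern_k`
#'   (default 20, selected from the top `top_k`).
#' @param cluster List with `k` (default: number of indicators of the active
#'   lexicon), `nstart`, `tol`, `max_iter`, `seeds_per_dimension` (for the
#'   ground-truth lexicon of synthetic corpora).
#' @param concern List with `thresholds = c(low, high)`.
#' @param hmm List with `spec` (an `hmm_spec`; default
#'   [opinion_policy_hmm()]), `n_runs` (default 10) and optional `n_steps`
#'   (default: the number of checkpoints).
#' @param seed Master seed.
#' @return An object of class `pipeline_config`.
#' @examples
#' cfg <- pipeline_config(seed = 1)
#' @export
pipeline_config <- function(events = NULL, generator = list(),
                            tfidf = list(), cluster = list(),
                            concern = list(), hmm = list(), seed = 1L) {
  if (is.null(events)) {
    defaults <- list(
      list(name = "guizhou_accident", n_docs = 1097L,
           original_weight = 0.73),
      list(name = "new_20_rules", n_docs = 1844L, original_weight = 0.37),
      list(name = "xinjiang_fire", n_docs = 3980L, original_weight = 0.35),
      list(name = "zhejiang_policy", n_docs = 622L, original_weight = 0.29))
    events <- defaults
  }
  events <- lapply(events, function(ev) {
    if (is.null(ev$name) || is.null(ev$n_docs))
      stop("each event needs `name` and `n_docs`")
    if (is.null(ev$dimension_weights)) {
      w <- ev$original_weight
      if (is.null(w)) stop("event '", ev$name,
                           "': need dimension_weights or original_weight")
      if (!is_prob(w)) stop("original_weight must be in [0, 1]")
      ev$dimension_weights <- c(w, (1 - w) * c(0.5, 0.25, 0.25))
    }
    ev
  })
  tfidf <- utils::modifyList(
    list(mode = "standard", top_k = 100L, concern_k = 20L), tfidf)
  cluster <- utils::modifyList(
    list(k = NULL, nstart = 10L, tol = 1e-8, max_iter = 300L,
         seeds_per_dimension = 8L), cluster)
  concern <- utils::modifyList(
    list(thresholds = c(low = 0.4, high = 0.6)), concern)
  hmm <- utils::modifyList(
    list(spec = NULL, n_runs = 10L, n_steps = NULL), hmm)
  hmm$spec <- hmm$spec %||% opinion_policy_hmm()
  if (!inherits(hmm$spec, "hmm_spec")) stop("hmm$spec must be an hmm_spec")
  # validate every generator block up front, before any stage runs
  for (ev in events) {
    do.call(corpus_config,
            c(list(event = ev$name, n_docs = ev$n_docs,
                   dimension_weights = ev$dimension_weights, seed = 1L),
              generator))
  }
  if (!is_count(tfidf$top_k) || !is_count(tfidf$concern_k))
    stop("tfidf top_k and concern_k must be positive integers")
  opinion_state(0.5, concern$thresholds) # validates thresholds
  if (!is_count(hmm$n_runs)) stop("hmm n_runs must be a positive integer")
  structure(list(events = events, generator = generator, tfidf = tfidf,
                 cluster = cluster, concern = concern, hmm = hmm,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
}

#' Run the full opinion-to-policy pipeline
#'
#' For every event checkpoint: generate a synthetic corpus, extract TF-IDF
#' keywords (top `top_k`, then top `concern_k` restricted to them), cluster
#' the top keywords, label clusters with the ground-truth lexicon, compute
#' the concern profile and satisfaction. The chronological satisfaction
#' series is discretised into the opinion observation sequence, the
#' opinion-policy HMM ensemble is simulated over the checkpoints, and the
#' hidden policy-intent state is filtered from the observed sequence. Every
#' artifact is written under `output_dir` and hashed into a manifest.
#'
#' @param config A [pipeline_config()].
#' @param output_dir Output directory (created if missing).
#' @return Invisibly, the manifest: list with `seed`, `stage_seeds`,
#'   `files` (name -> md5), plus summary fields. Also written as
#'   `manifest.json`.
#' @export
run_pipeline <- function(config, output_dir) {
  if (!inherits(config, "pipeline_config"))
    stop("`config` must be a pipeline_config")
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  put <- function(name) files <<- c(files, name)
  stage_seeds <- list()
  profiles <- list()
  event_rows <- list()

  for (ev in config$events) {
    nm <- ev$name
    gseed <- derive_seed(config$seed, paste0("generate/", nm))
    stage_seeds[[paste0("generate/", nm)]] <- gseed
    corpus <- stage("generate", {
      cfg <- do.call(corpus_config,
                     c(list(event = nm, n_docs = ev$n_docs,
                            dimension_weights = ev$dimension_weights,
                            seed = gseed),
                       config$generator))
      generate_corpus(cfg)
    })
    stage("generate", {
      write_corpus(corpus, file.path(output_dir,
                                     paste0(nm, ".jsonl")))
      put(paste0(nm, ".jsonl")); put(paste0(nm, ".jsonl.truth.json"))
    })

    kw100 <- stage("keywords", {
      stats <- tfidf_scores(corpus, mode = config$tfidf$mode)
      top_keywords(stats, config$tfidf$top_k)
    })
    kw20 <- stage("keywords",
                  top_keywords(kw100, config$tfidf$concern_k,
                               previous = kw100))
    stage("keywords", {
      write_keywords(kw100, file.path(output_dir,
                                      paste0(nm, "_top", config$tfidf$top_k,
                                             ".csv")))
      put(paste0(nm, "_top", config$tfidf$top_k, ".csv"))
      write_keywords(kw20, file.path(output_dir,
                                     paste0(nm, "_top",
                                            config$tfidf$concern_k, ".csv")))
      put(paste0(nm, "_top", config$tfidf$concern_k, ".csv"))
    })

    cl <- stage("cluster", {
      lex <- lexicon_from_truth(corpus, config$cluster$seeds_per_dimension)
      k <- config$cluster$k %||% nrow(lexicon_indicators(lex))
      wv <- build_word_vectors(corpus, kw100, mode = config$tfidf$mode)
      cseed <- derive_seed(config$seed, paste0("cluster/", nm))
      stage_seeds[[paste0("cluster/", nm)]] <- cseed
      res <- kmeans_lloyd(wv, k = k, seed = cseed,
                          tol = config$cluster$tol,
                          max_iter = config$cluster$max_iter,
                          nstart = config$cluster$nstart)
      mapping <- assign_clusters_to_indicators(res, lex)
      list(result = res, mapping = mapping,
           token_dims = token_dimension_map(res, mapping))
    })
    stage("cluster", {
      df <- data.frame(token = names(cl$result$assignments),
                       cluster = as.integer(cl$result$assignments),
                       stringsAsFactors = FALSE)
      df <- merge(df, cl$mapping, by = "cluster", sort = FALSE)
      df <- df[order(df$cluster, df$token),
               c("token", "cluster", "dimension", "indicator")]
      utils::write.csv(df, file.path(output_dir,
                                     paste0(nm, "_clusters.csv")),
                       row.names = FALSE)
      put(paste0(nm, "_clusters.csv"))
    })

    prof <- stage("concern", concern_profile(kw20, cl$token_dims,
                                             event = nm))
    profiles[[nm]] <- prof
    event_rows[[nm]] <- stage("concern", {
      data.frame(event = nm, t(prof$shares),
                 satisfaction = satisfaction(prof),
                 check.names = FALSE, stringsAsFactors = FALSE)
    })
  }

  concern_df <- do.call(rbind, event_rows)
  rownames(concern_df) <- NULL
  utils::write.csv(concern_df, file.path(output_dir, "concern_profiles.csv"),
                   row.names = FALSE)
  put("concern_profiles.csv")

  oseq <- stage("concern",
                opinion_sequence(profiles,
                                 thresholds = config$concern$thresholds))
  utils::write.csv(as.data.frame(oseq),
                   file.path(output_dir, "opinion_sequence.csv"),
                   row.names = FALSE)
  put("opinion_sequence.csv")
  jsonlite::write_json(as.data.frame(oseq),
                       file.path(output_dir, "opinion_sequence.json"),
                       digits = NA)
  put("opinion_sequence.json")

  hseed <- derive_seed(config$seed, "hmm")
  stage_seeds[["hmm"]] <- hseed
  n_steps <- config$hmm$n_steps %||% length(config$events)
  ens <- stage("hmm", simulate_ensemble(config$hmm$spec, n_steps,
                                        n_runs = config$hmm$n_runs,
                                        seed = hseed))
  utils::write.csv(as.data.frame(ens),
                   file.path(output_dir, "hmm_ensemble.csv"),
                   row.names = FALSE)
  put("hmm_ensemble.csv")
  filt <- stage("hmm", forward_filter(config$hmm$spec, oseq$state))
  post <- data.frame(t = seq_len(nrow(filt$posterior)), filt$posterior,
                     check.names = FALSE)
  utils::write.csv(post, file.path(output_dir, "policy_posterior.csv"),
                   row.names = FALSE)
  put("policy_posterior.csv")

  manifest <- list(
    package = "opinionflow",
    version = as.character(utils::packageVersion("opinionflow")),
    seed = config$seed,
    stage_seeds = stage_seeds,
    n_events = length(config$events),
    log_likelihood = filt$log_likelihood,
    files = as.list(stats::setNames(
      unname(tools::md5sum(file.path(output_dir, files))), files)))
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
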
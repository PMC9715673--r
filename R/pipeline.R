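# End-to-end synthetic benchmark: generate phantoms, train the three
# classifiers (CNN on raw images; IG on the CNN's Deep Taylor maps; ATT with
# the attention head), rank every query/catalogue split under all five
# comparators, and score with nDCG. Every artifact carries provenance
# (config hash, seed, package version) sufficient to re-run bit-identically.

stop_invariant <- function(...) stop(structure(
  class = c("saliret_invariant_error", "error", "condition"),
  list(message = sprintf(...), call = sys.call(-1))))

#' Benchmark run configuration
#'
#' One object holding the phantom generator settings, the dataset partition,
#' the per-model training protocols and the evaluation protocol. The global
#' `seed` is propagated (by derivation) to every stochastic component.
#'
#' @param phantom a [phantom_config()]; its seed is overridden by `seed`.
#' @param n_train,n_val,n_test dataset partition sizes.
#' @param n_queries,p retrieval protocol: number of query/catalogue splits
#'   and catalogue size.
#' @param p_evals nDCG truncation depths.
#' @param methods retrieval methods to benchmark.
#' @param train_cnn,train_ig,train_att [train_config()]s per model; seeds
#'   are overridden by derivations of `seed`.
#' @param seed global integer seed.
#' @export
run_config <- function(phantom = phantom_config(),
                       n_train = 600L, n_val = 100L, n_test = 100L,
                       n_queries = 10L, p = 10L, p_evals = c(10L, 3L),
                       methods = c("ssim", "cnn", "cnn_ig", "ig", "att"),
                       train_cnn = train_config(optimizer = "adam",
                                                learning_rate = 5e-3,
                                                clip_norm = 10),
                       train_ig = train_config(optimizer = "adam",
                                               learning_rate = 5e-3,
                                                clip_norm = 10),
                       train_att = train_config(optimizer = "adam",
                                                learning_rate = 5e-3,
                                                clip_norm = 10),
                       seed = 1L) {
  methods <- match.arg(methods, c("ssim", "cnn", "cnn_ig", "ig", "att"),
                       several.ok = TRUE)
  if (n_train < 2L || n_val < 1L || n_test < 2L)
    stop_config("invalid config: dataset partition sizes too small")
  phantom$seed <- derive_seed(seed, 100L)
  train_cnn$seed <- derive_seed(seed, 201L)
  train_ig$seed <- derive_seed(seed, 202L)
  train_att$seed <- derive_seed(seed, 203L)
  structure(list(phantom = phantom, n_train = as.integer(n_train),
                 n_val = as.integer(n_val), n_test = as.integer(n_test),
                 n_queries = as.integer(n_queries), p = as.integer(p),
                 p_evals = as.integer(p_evals), methods = methods,
                 train_cnn = train_cnn, train_ig = train_ig,
                 train_att = train_att, seed = as.integer(seed)),
            class = "run_config")
}

#' Load a run configuration from a YAML or JSON file
#'
#' Recognised top-level keys mirror the arguments of [run_config()];
#' `phantom` and `train_*` entries are passed to their constructors, so any
#' field those accept can be overridden.
#' @param path `.yaml`/`.yml` or `.json` file.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) stop_config("config file not found: %s", path)
  raw <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop_config("yaml package required to read %s", path)
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  args <- list()
  if (!is.null(raw$phantom)) args$phantom <- do.call(phantom_config, raw$phantom)
  for (f in c("n_train", "n_val", "n_test", "n_queries", "p", "p_evals",
              "methods", "seed"))
    if (!is.null(raw[[f]])) args[[f]] <- raw[[f]]
  for (f in c("train_cnn", "train_ig", "train_att"))
    if (!is.null(raw[[f]])) args[[f]] <- do.call(train_config, raw[[f]])
  do.call(run_config, args)
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(config, f)
  unname(tools::md5sum(f))
}

partition_ids <- function(samples, config) {
  ids <- vapply(samples, `[[`, "", "sample_id")
  n <- length(ids)
  need <- config$n_train + config$n_val + config$n_test
  if (n < need) stop_data("dataset has %d samples, need %d", n, need)
  list(train = ids[seq_len(config$n_train)],
       val = ids[config$n_train + seq_len(config$n_val)],
       test = ids[config$n_train + config$n_val + seq_len(config$n_test)])
}

#' Generate the benchmark dataset on disk
#'
#' Generates `n_train + n_val + n_test` phantoms, builds the query/catalogue
#' splits from the test partition, and writes the manifest plus a
#' provenance file (`run.json`: config hash, seed, package version,
#' partition).
#'
#' @param config a [run_config()].
#' @param dir output directory.
#' @return the directory, invisibly.
#' @export
run_generate <- function(config, dir) {
  n <- config$n_train + config$n_val + config$n_test
  samples <- generate_dataset(config$phantom, n)
  part <- partition_ids(samples, config)
  names(samples) <- vapply(samples, `[[`, "", "sample_id")
  splits <- make_splits(samples[part$test], config$n_queries, config$p,
                        seed = derive_seed(config$seed, 300L))
  write_manifest(samples, splits, dir)
  jsonlite::write_json(
    list(config_hash = config_hash(config), seed = config$seed,
         package_version = as.character(utils::packageVersion("saliret")),
         n = n, class_balance = config$phantom$class_balance,
         partition = part),
    file.path(dir, "run.json"), auto_unbox = TRUE, digits = NA)
  message(sprintf("generated %d phantoms (%d positive), %d splits", n,
                  sum(vapply(samples, `[[`, 1L, "label") == 1L),
                  length(splits)))
  invisible(dir)
}

load_run <- function(dir) {
  rj <- file.path(dir, "run.json")
  if (!file.exists(rj)) stop_data("no run.json in %s; run run_generate first", dir)
  meta <- jsonlite::read_json(rj, simplifyVector = TRUE)
  mani <- read_manifest(dir)
  list(meta = meta, samples = mani$samples, splits = mani$splits)
}

subset_dataset <- function(samples, ids) {
  s <- samples[ids]
  list(images = lapply(s, `[[`, "image"),
       labels = vapply(s, function(x) as.integer(x$label), 1L))
}

# Deep Taylor maps of a trained raw-image model, as 2-D training inputs.
saliency_dataset <- function(cnn, ds, cache = NULL) {
  n <- length(ds$images)
  imgs <- vector("list", n)
  ids <- names(ds$images)
  for (i in seq_len(n)) {
    s <- cached_saliency(cnn, ds$images[[i]],
                         if (is.null(ids)) as.character(i) else ids[i], cache)
    m <- s$relevance
    mx <- max(m)
    if (mx > 0) m <- m / mx
    imgs[[i]] <- m
  }
  list(images = imgs, labels = ds$labels)
}

#' Train one benchmark model
#'
#' `model_id = "cnn"` trains the raw-image classifier, `"ig"` trains the
#' same architecture on the CNN's Deep Taylor saliency maps (the CNN
#' checkpoint must exist first: it is the saliency source), `"att"` trains
#' the attention model on raw images. Writes `<model_id>.rds` (+ JSON
#' sidecar) and `<model_id>_log.csv` into `dir`.
#'
#' @param config a [run_config()].
#' @param dir dataset directory from [run_generate()].
#' @param model_id `"cnn"`, `"ig"` or `"att"`.
#' @return `list(model, log)`, invisibly.
#' @export
run_train <- function(config, dir, model_id = c("cnn", "ig", "att")) {
  model_id <- match.arg(model_id)
  run <- load_run(dir)
  part <- run$meta$partition
  tr <- subset_dataset(run$samples, part$train)
  va <- subset_dataset(run$samples, part$val)
  if (model_id == "cnn") {
    model <- build_backbone("tiny", seed = derive_seed(config$seed, 401L))
    fit <- train(model, tr, va, config$train_cnn)
  } else if (model_id == "ig") {
    cnn_path <- file.path(dir, "cnn.rds")
    if (!file.exists(cnn_path))
      stop_config("training 'ig' requires the cnn checkpoint (its saliency source); train cnn first")
    cnn <- load_checkpoint(cnn_path)
    cache <- new.env(parent = emptyenv())
    tr_s <- saliency_dataset(cnn, tr, cache)
    va_s <- saliency_dataset(cnn, va, cache)
    model <- build_backbone("tiny", seed = derive_seed(config$seed, 402L))
    fit <- train(model, tr_s, va_s, config$train_ig)
    fit$model$meta$saliency_source <- cnn$meta$fingerprint
  } else {
    model <- build_attention_model(
      "tiny", config = attention_config(seed = derive_seed(config$seed, 403L)))
    fit <- train(model, tr, va, config$train_att)
  }
  save_checkpoint(fit$model, file.path(dir, paste0(model_id, ".rds")))
  write.csv(fit$log, file.path(dir, paste0(model_id, "_log.csv")),
            row.names = FALSE)
  message(sprintf("%s: selected epoch %d, validation F1 %.3f", model_id,
                  fit$model$meta$selected_epoch, fit$model$meta$val_f1))
  invisible(fit)
}

needed_model_ids <- function(methods)
  unique(unlist(lapply(methods, required_models)))

#' Rank all splits under the configured methods
#'
#' Loads (or trains, if `train_missing`) the required checkpoints, ranks
#' every split under every method and writes `retrieval.csv`.
#'
#' @inheritParams run_train
#' @param train_missing train any missing required checkpoint in dependency
#'   order instead of failing.
#' @return list of `retrieval_result`, invisibly.
#' @export
run_retrieve <- function(config, dir, train_missing = TRUE) {
  run <- load_run(dir)
  models <- list()
  for (mid in needed_model_ids(config$methods)) {
    path <- file.path(dir, paste0(mid, ".rds"))
    if (!file.exists(path)) {
      if (!train_missing) stop_config("missing checkpoint for '%s'", mid)
      run_train(config, dir, mid)
    }
    models[[mid]] <- load_checkpoint(path)
  }
  images <- lapply(run$samples, `[[`, "image")
  cache <- new.env(parent = emptyenv())
  results <- list()
  for (sp in run$splits) {
    for (m in config$methods) {
      r <- rank_catalogue(sp, m, images, models, saliency_cache = cache)
      if (!setequal(r$ranking, sp$catalogue_ids))
        stop_invariant("ranking for %s/%s is not a catalogue permutation",
                       sp$split_id, m)
      results[[length(results) + 1L]] <- r
    }
  }
  write_retrieval_results(results, file.path(dir, "retrieval.csv"))
  invisible(results)
}

#' Run the full synthetic retrieval benchmark
#'
#' Dataset generation (if needed), training of all required models,
#' retrieval under every configured method, and nDCG evaluation at the
#' configured truncations. Writes `ndcg_per_split.csv` and
#' `ndcg_summary.csv` into `dir`.
#'
#' @inheritParams run_train
#' @return the evaluation result of [evaluate_methods()].
#' @export
run_benchmark <- function(config, dir) {
  if (!file.exists(file.path(dir, "run.json"))) run_generate(config, dir)
  results <- run_retrieve(config, dir)
  run <- load_run(dir)
  ev <- evaluate_methods(run$splits, results, p_evals = config$p_evals)
  write.csv(ev$per_split, file.path(dir, "ndcg_per_split.csv"),
            row.names = FALSE)
  write.csv(ev$summary, file.path(dir, "ndcg_summary.csv"), row.names = FALSE)
  ev
}

#' Export saliency maps for every image of a partition
#'
#' @inheritParams run_train
#' @param partition `"train"`, `"val"` or `"test"`.
#' @return directory of written maps, invisibly.
#' @export
run_saliency <- function(config, dir, partition = "test") {
  run <- load_run(dir)
  cnn_path <- file.path(dir, "cnn.rds")
  if (!file.exists(cnn_path)) run_train(config, dir, "cnn")
  cnn <- load_checkpoint(cnn_path)
  out <- file.path(dir, "saliency")
  dir.create(out, showWarnings = FALSE)
  ids <- run$meta$partition[[partition]]
  for (id in ids) {
    s <- deep_taylor(cnn, run$samples[[id]]$image, sample_id = id)
    write_saliency(s, file.path(out, paste0(id, ".tiff")))
  }
  invisible(out)
}
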
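# Catalogue ranking under each comparator:
#   ssim   - structural similarity between raw images (higher = more similar)
#   cnn    - Euclidean distance between penultimate features of the
#            raw-image classifier
#   cnn_ig - distances between raw-image-classifier features of Deep Taylor
#            saliency maps (ablation: maps used only at retrieval time)
#   ig     - distances between saliency-trained-model features of Deep
#            Taylor saliency maps
#   att    - distances between attention-model fused features

#' Structural similarity index (SSIM)
#'
#' Mean local SSIM with the original formulation's defaults: 11x11 Gaussian
#' window with sigma 1.5, K1 = 0.01, K2 = 0.03, dynamic range 1. Computed on
#' raw grayscale images at native resolution; symmetric in its arguments.
#'
#' @param image_a,image_b equal-sized matrices with values in \[0, 1\].
#' @export
ssim <- function(image_a, image_b) {
  if (!identical(dim(image_a), dim(image_b)))
    stop_data("ssim: images must have identical dimensions")
  H <- nrow(image_a); W <- ncol(image_a)
  win <- 11L
  if (H < win || W < win)
    stop_data("ssim: images must be at least %dx%d", win, win)
  g <- exp(-((seq_len(win) - (win + 1) / 2)^2) / (2 * 1.5^2))
  k <- outer(g, g); k <- as.numeric(k / sum(k))
  colsA <- cpp_im2col(array(image_a, c(H, W, 1L)), H, W, 1L, win, win, 1L, 0L)
  colsB <- cpp_im2col(array(image_b, c(H, W, 1L)), H, W, 1L, win, win, 1L, 0L)
  mu1 <- drop(colsA %*% k); mu2 <- drop(colsB %*% k)
  s1 <- drop((colsA * colsA) %*% k) - mu1^2
  s2 <- drop((colsB * colsB) %*% k) - mu2^2
  s12 <- drop((colsA * colsB) %*% k) - mu1 * mu2
  C1 <- 0.01^2; C2 <- 0.03^2
  mean(((2 * mu1 * mu2 + C1) * (2 * s12 + C2)) /
       ((mu1^2 + mu2^2 + C1) * (s1 + s2 + C2)))
}

#' Euclidean distance between feature vectors
#' @param feat_a,feat_b equal-length numeric vectors.
#' @export
pairwise_distance <- function(feat_a, feat_b) {
  if (length(feat_a) != length(feat_b))
    stop_data("feature vectors have different lengths (%d vs %d)",
              length(feat_a), length(feat_b))
  sqrt(sum((feat_a - feat_b)^2))
}

#' Retrieval method specification
#'
#' @param method_id one of `"ssim"`, `"cnn"`, `"cnn_ig"`, `"ig"`, `"att"`.
#' @export
method_spec <- function(method_id = c("ssim", "cnn", "cnn_ig", "ig", "att")) {
  structure(list(method_id = match.arg(method_id)), class = "method_spec")
}

required_models <- function(method_id)
  switch(method_id, ssim = character(), cnn = "cnn", cnn_ig = "cnn",
         ig = c("cnn", "ig"), att = "att")

# Saliency maps are cached per (model fingerprint, sample id).
cached_saliency <- function(model, image, sample_id, cache) {
  if (is.null(cache)) return(deep_taylor(model, image, sample_id))
  fp <- model$meta$fingerprint
  if (is.null(fp)) fp <- "unfingerprinted"
  key <- paste(fp, sample_id, sep = "|")
  if (is.null(cache[[key]]))
    cache[[key]] <- deep_taylor(model, image, sample_id)
  cache[[key]]
}

#' Rank a catalogue against a query
#'
#' Scores every catalogue image against the split's query under the chosen
#' method and returns the catalogue as a permutation ordered from most to
#' least similar. Distance methods sort ascending, SSIM descending; exact
#' score ties are broken by ascending sample id.
#'
#' @param split a `qc_split`.
#' @param method a [method_spec()] or method id string.
#' @param images named list of grayscale matrices covering the query and the
#'   whole catalogue.
#' @param models named list of trained models (`cnn`, `ig`, `att` as the
#'   method requires).
#' @param saliency_cache optional environment reused across calls to avoid
#'   recomputing Deep Taylor maps.
#' @return `retrieval_result`: `list(split_id, method_id, ranking, scores)`
#'   with `scores` named by sample id in rank order.
#' @export
rank_catalogue <- function(split, method, images, models = list(),
                           saliency_cache = NULL) {
  if (is.character(method)) method <- method_spec(method)
  mid <- method$method_id
  need <- required_models(mid)
  miss <- need[!need %in% names(models)]
  if (length(miss) > 0L)
    stop_config("method '%s' requires model checkpoint(s): %s", mid,
                paste(miss, collapse = ", "))
  ids <- split$catalogue_ids
  all_ids <- c(split$query_id, ids)
  if (!all(all_ids %in% names(images)))
    stop_data("images missing for: %s",
              paste(setdiff(all_ids, names(images)), collapse = ", "))

  embed <- function(id) {
    img <- images[[id]]
    switch(mid,
      cnn = extract_features(models$cnn, img),
      cnn_ig = {
        s <- cached_saliency(models$cnn, img, id, saliency_cache)
        extract_features(models$cnn, to_input_image(s, models$cnn$input_spec))
      },
      ig = {
        s <- cached_saliency(models$cnn, img, id, saliency_cache)
        extract_features(models$ig, to_input_image(s, models$ig$input_spec))
      },
      att = extract_features(models$att, img))
  }

  if (mid == "ssim") {
    q <- images[[split$query_id]]
    scores <- vapply(ids, function(id) ssim(q, images[[id]]), 1.0)
    ord <- order(-scores, ids)
  } else {
    fq <- embed(split$query_id)
    scores <- vapply(ids, function(id) pairwise_distance(fq, embed(id)), 1.0)
    ord <- order(scores, ids)
  }
  structure(list(split_id = split$split_id, method_id = mid,
                 ranking = ids[ord], scores = scores[ord]),
            class = "retrieval_result")
}

#' Write retrieval results as CSV
#'
#' One row per rank: `split_id,method_id,rank,sample_id,score`.
#' @param results list of `retrieval_result`.
#' @param path output CSV path.
#' @export
write_retrieval_results <- function(results, path) {
  rows <- do.call(rbind, lapply(results, function(r)
    data.frame(split_id = r$split_id, method_id = r$method_id,
               rank = seq_along(r$ranking), sample_id = r$ranking,
               score = as.numeric(r$scores), stringsAsFactors = FALSE)))
  write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
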
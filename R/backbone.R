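#' Build a binary-classification CNN backbone
#'
#' Constructs an untrained convolutional classifier ending in global average
#' pooling, a penultimate feature vector and a single sigmoid output. Two
#' architectures are available: `"tiny"`, a reduced densely connected
#' network sized for CPU training on phantom radiographs (penultimate width
#' `feature_dim`, default 64), and `"densenet121"`, the standard DenseNet-121
#' topology (growth 32, blocks 6/12/24/16) whose penultimate vector has
#' dimension 1024. Weights are He-initialised from `seed`; no external
#' pretraining is used.
#'
#' @param architecture_id `"tiny"` or `"densenet121"`.
#' @param input_spec integer vector `c(height, width, channels)`. Defaults to
#'   `c(96, 96, 1)` for tiny and `c(224, 224, 3)` for densenet121.
#' @param feature_dim penultimate width for the tiny architecture.
#' @param seed integer seed for weight initialisation.
#' @return an object of class `sal_model` (untrained).
#' @export
build_backbone <- function(architecture_id = c("tiny", "densenet121"),
                           input_spec = NULL, feature_dim = 64L, seed = 1L) {
  architecture_id <- tryCatch(match.arg(architecture_id),
                              error = function(e)
                                stop_config("unknown architecture '%s'",
                                            architecture_id[1]))
  if (is.null(input_spec))
    input_spec <- if (architecture_id == "tiny") c(96L, 96L, 1L)
                  else c(224L, 224L, 3L)
  input_spec <- as.integer(input_spec)
  if (length(input_spec) != 3L || any(is.na(input_spec)))
    stop_config("input_spec must be c(height, width, channels)")
  if (input_spec[3] < 1L) stop_config("input_spec: channels must be >= 1")
  if (any(input_spec[1:2] < 32L)) stop_config("input_spec: image side must be >= 32")

  with_seed(seed, {
    if (architecture_id == "tiny")
      m <- build_tiny(input_spec, as.integer(feature_dim))
    else
      m <- build_densenet121(input_spec)
  })
  m$architecture_id <- architecture_id
  m$input_spec <- input_spec
  m$seed <- as.integer(seed)
  m$trained <- FALSE
  m$head <- NULL
  m$meta <- list()
  class(m) <- "sal_model"
  m
}

tiny_unit <- function(in_ch, growth = 16L)
  layer_dense_unit(list(layer_ebn(in_ch), layer_relu(),
                        layer_conv(3L, 3L, in_ch, growth, pad = 1L)), growth)

# The reduced dense-block classifier. Normalisation uses running (global)
# statistics, as conventional batch norm does at inference, so activation
# maps keep the spatial and inter-sample contrast that relevance
# propagation relies on.
build_tiny <- function(input_spec, feature_dim) {
  if (feature_dim < 1L) stop_config("feature_dim must be >= 1")
  layers <- list(
    layer_conv(3L, 3L, input_spec[3], 16L, stride = 2L, pad = 1L),
    layer_ebn(16L),
    layer_relu(),
    layer_pool("max"),
    layer_pool("max"),
    tiny_unit(16L),            # -> 32 channels
    tiny_unit(32L),            # -> 48 channels (first-block tap)
    layer_ebn(48L),
    layer_relu(),
    layer_conv(1L, 1L, 48L, 32L),  # transition (channel compression only:
                                   # spatial detail is kept for attribution)
    tiny_unit(32L),            # -> 48 channels
    tiny_unit(48L))            # -> 64 channels (deep tap)
  taps <- c(7L, 12L)
  if (feature_dim != 64L) {
    layers <- c(layers, list(layer_relu(),
                             layer_conv(1L, 1L, 64L, as.integer(feature_dim))))
  }
  head <- layer_dense(feature_dim, 1L)
  head$W <- head$W * 0.1   # near-symmetric start for the sigmoid head
  layers <- c(layers, list(layer_ebn(feature_dim), layer_relu(), layer_gap(),
                           layer_scale(4), head))
  # per-image intensity standardisation: the usual radiograph preprocessing,
  # removing exposure/gain nuisance before the first convolution
  list(layers = layers, taps = taps, gap_index = length(layers) - 1L,
       feature_dim = as.integer(feature_dim), input_norm = TRUE)
}

dn_unit <- function(in_ch, growth = 32L, bottleneck = 4L * growth)
  layer_dense_unit(list(
    layer_bn(in_ch), layer_relu(), layer_conv(1L, 1L, in_ch, bottleneck),
    layer_bn(bottleneck), layer_relu(),
    layer_conv(3L, 3L, bottleneck, growth, pad = 1L)), growth)

build_densenet121 <- function(input_spec) {
  growth <- 32L
  blocks <- c(6L, 12L, 24L, 16L)
  layers <- list(
    layer_conv(7L, 7L, input_spec[3], 64L, stride = 2L, pad = 3L),
    layer_bn(64L), layer_relu(),
    layer_pool("max", 3L, 3L, 2L, 1L))
  ch <- 64L
  taps <- integer(0)
  for (b in seq_along(blocks)) {
    for (i in seq_len(blocks[b])) {
      layers <- c(layers, list(dn_unit(ch, growth)))
      ch <- ch + growth
    }
    if (b >= 2L) taps <- c(taps, length(layers))
    if (b < length(blocks)) {
      half <- ch %/% 2L
      layers <- c(layers, list(layer_bn(ch), layer_relu(),
                               layer_conv(1L, 1L, ch, half),
                               layer_pool("avg")))
      ch <- half
    }
  }
  layers <- c(layers, list(layer_bn(ch), layer_relu(), layer_gap(),
                           layer_dense(ch, 1L)))
  list(layers = layers, taps = taps, gap_index = length(layers) - 1L,
       feature_dim = ch)
}

# ---- forward / backward ----------------------------------------------------

sigmoid <- function(z) 1 / (1 + exp(-z))

backbone_forward <- function(model, x, upto = length(model$layers),
                             keep_out = FALSE) {
  caches <- vector("list", upto)
  outs <- if (keep_out) vector("list", upto) else NULL
  h <- x
  for (i in seq_len(upto)) {
    r <- layer_forward(model$layers[[i]], h)
    caches[[i]] <- r$cache
    h <- r$y
    if (keep_out) outs[[i]] <- h
  }
  list(out = h, caches = caches, outs = outs)
}

backbone_backward <- function(model, caches, g_out, upto = length(model$layers),
                              tap_grads = NULL) {
  grads <- vector("list", length(model$layers))
  g <- g_out
  for (i in rev(seq_len(upto))) {
    if (!is.null(tap_grads) && !is.null(tap_grads[[i]]))
      g <- g + tap_grads[[i]]
    r <- layer_backward(model$layers[[i]], caches[[i]], g)
    grads[i] <- list(r$grads)
    g <- r$gx
  }
  list(grads = grads, gx = g)
}

# Full forward through either architecture head.
model_forward <- function(model, x, keep = FALSE) {
  if (is.null(model$head)) {
    fw <- backbone_forward(model, x, keep_out = TRUE)
    logit <- as.numeric(fw$out)
    feature <- fw$outs[[model$gap_index]]
    list(logit = logit, prob = sigmoid(logit), feature = feature, bb = fw)
  } else {
    upto <- max(model$head$tap_layers)
    fw <- backbone_forward(model, x, upto = upto, keep_out = TRUE)
    taps <- fw$outs[model$head$tap_layers]
    hf <- att_head_forward(model$head, taps)
    list(logit = hf$logit, prob = sigmoid(hf$logit), feature = hf$feature,
         bb = fw, head = hf)
  }
}

model_backward <- function(model, fw, g_logit) {
  if (is.null(model$head)) {
    bw <- backbone_backward(model, fw$bb$caches, array(g_logit, 1L))
    list(layers = bw$grads, head = NULL)
  } else {
    hb <- att_head_backward(model$head, fw$head, g_logit)
    upto <- max(model$head$tap_layers)
    tap_grads <- vector("list", length(model$layers))
    for (k in seq_along(model$head$tap_layers))
      tap_grads[[model$head$tap_layers[k]]] <- hb$g_taps[[k]]
    last <- model$head$tap_layers[length(model$head$tap_layers)]
    tap_grads_last <- tap_grads[[last]]
    tap_grads[last] <- list(NULL)
    bw <- backbone_backward(model, fw$bb$caches, tap_grads_last, upto = upto,
                            tap_grads = tap_grads)
    list(layers = bw$grads, head = hb$grads)
  }
}

get_params <- function(model)
  list(layers = lapply(model$layers, layer_params),
       head = if (!is.null(model$head)) att_head_params(model$head))

set_params <- function(model, p) {
  for (i in seq_along(model$layers))
    model$layers[[i]] <- layer_set_params(model$layers[[i]], p$layers[[i]])
  if (!is.null(model$head))
    model$head <- att_head_set_params(model$head, p$head)
  model
}

model_fingerprint <- function(model) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(get_params(model), f)
  unname(tools::md5sum(f))
}

# Resize to the model grid and replicate grayscale across input channels.
prepare_input <- function(model, image) {
  if (is.matrix(image)) image <- array(image, c(dim(image), 1L))
  d <- dim(image)
  if (length(d) != 3L)
    stop_data("image must be a 2-D matrix or (H, W, C) array")
  spec <- model$input_spec
  if (d[3] != spec[3] && d[3] != 1L)
    stop_data("image has %d channels but the model expects %d", d[3], spec[3])
  if (d[1] != spec[1] || d[2] != spec[2])
    image <- cpp_resize_bilinear(image, d[1], d[2], d[3], spec[1], spec[2])
  if (dim(image)[3] == 1L && spec[3] > 1L)
    image <- array(rep(as.numeric(image), spec[3]), spec)
  if (!is.null(model$center))
    image <- image - as.numeric(model$center)
  if (isTRUE(model$input_norm)) {
    # gain normalisation: dividing by the mean intensity cancels global
    # exposure/gain differences while preserving local lesion contrast
    mu <- mean(image) + 1e-6
    image <- image / mu
    # the [0, 1] pixel domain mapped through this image's normalisation,
    # for the bounded input rule of relevance propagation
    attr(image, "pixel_bounds") <- list(low = 0, high = 1 / mu)
  }
  image
}

# Mean image over a dataset, on the model's input grid (single channel).
compute_center <- function(model, images) {
  spec <- model$input_spec
  acc <- matrix(0, spec[1], spec[2])
  for (img in images) {
    if (is.matrix(img)) img <- array(img, c(dim(img), 1L))
    d <- dim(img)
    if (d[1] != spec[1] || d[2] != spec[2])
      img <- cpp_resize_bilinear(img, d[1], d[2], d[3], spec[1], spec[2])
    acc <- acc + matrix(img[, , 1L], spec[1], spec[2])
  }
  acc / length(images)
}

#' Penultimate-layer feature vector of an image
#'
#' Runs the model in inference mode (no augmentation, deterministic) and
#' returns the global-average-pooled penultimate activation vector used as
#' the image embedding for retrieval distances.
#'
#' @param model a `sal_model`.
#' @param image grayscale matrix (values in \[0, 1\]) or (H, W, C) array.
#' @return numeric vector of length `model$feature_dim`.
#' @export
extract_features <- function(model, image) {
  x <- prepare_input(model, image)
  model_forward(model, x)$feature
}

#' @export
predict_prob <- function(model, image) {
  x <- prepare_input(model, image)
  model_forward(model, x)$prob
}

# ---- loss and selection metric --------------------------------------------

#' Class-weighted binary cross-entropy
#'
#' `-w_y (y ln p + (1 - y) ln(1 - p))` with the probability clamped to
#' `[1e-7, 1 - 1e-7]`. With unit weights this is the plain binary
#' cross-entropy. Vectorised; returns one loss per element.
#'
#' @param y binary labels (0/1).
#' @param p predicted probabilities.
#' @param weights length-2 vector `c(w_negative, w_positive)`.
#' @export
weighted_bce <- function(y, p, weights = c(1, 1)) {
  if (!all(y %in% c(0, 1))) stop_data("labels must be 0 or 1")
  if (length(p) != length(y)) stop_data("y and p must have equal length")
  eps <- 1e-7
  p <- pmin(pmax(p, eps), 1 - eps)
  w <- weights[y + 1L]
  -w * (y * log(p) + (1 - y) * log(1 - p))
}

#' Inverse-frequency class weights
#'
#' `w_c = N / (2 N_c)`, normalised so a balanced set yields unit weights.
#' @param labels binary labels.
#' @return `c(w_negative, w_positive)`.
#' @export
class_weights <- function(labels) {
  n <- length(labels)
  n1 <- sum(labels == 1)
  n0 <- n - n1
  if (n0 == 0L || n1 == 0L)
    stop_data("class weighting needs both classes present")
  c(n / (2 * n0), n / (2 * n1))
}

#' F1 score at a probability threshold
#'
#' `2 * precision * recall / (precision + recall)`; defined as 0 when
#' `precision + recall = 0`.
#' @param predictions probabilities.
#' @param labels binary labels.
#' @param threshold decision threshold (default 0.5).
#' @export
f1_score <- function(predictions, labels, threshold = 0.5) {
  if (length(predictions) == 0L) stop_data("empty predictions")
  if (length(predictions) != length(labels))
    stop_data("predictions and labels must have equal length")
  yhat <- as.integer(predictions >= threshold)
  tp <- sum(yhat == 1 & labels == 1)
  fp <- sum(yhat == 1 & labels == 0)
  fn <- sum(yhat == 0 & labels == 1)
  prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
  rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
  if (prec + rec == 0) return(0)
  2 * prec * rec / (prec + rec)
}

# ---- training --------------------------------------------------------------

#' Training configuration
#'
#' Defaults follow the package's pleural-effusion-style protocol: 10 epochs,
#' batch size 32, Adadelta, inverse-frequency class weighting, augmentation
#' by rotations up to 10 degrees and translations up to 5% of the image side.
#' The Adam learning rate (used when `optimizer = "adam"`) defaults to 1e-4.
#'
#' @param epochs,batch_size training schedule.
#' @param optimizer `"adadelta"` or `"adam"`.
#' @param learning_rate Adam step size.
#' @param class_weighting weight the loss by inverse class frequency.
#' @param aug_rotate,aug_translate augmentation ranges (degrees; fraction of side).
#' @param clip_norm global gradient-norm clip per batch (0 disables).
#' @param lr_decay per-epoch step-size scaling: a single multiplicative decay
#'   factor (1 = constant), or a numeric vector of per-epoch scale factors
#'   (e.g. a warm-restart cosine schedule), recycled over epochs.
#' @param init_from optional trained `sal_model` used as warm start.
#' @param seed integer seed for shuffling and augmentation.
#' @export
train_config <- function(epochs = 10L, batch_size = 32L,
                         optimizer = c("adadelta", "adam"),
                         learning_rate = 1e-4, class_weighting = TRUE,
                         aug_rotate = 10, aug_translate = 0.05,
                         clip_norm = 5, lr_decay = 1, init_from = NULL, seed = 1L) {
  optimizer <- match.arg(optimizer)
  if (epochs < 1L) stop_config("epochs must be >= 1")
  if (batch_size < 1L) stop_config("batch_size must be >= 1")
  if (optimizer == "adam" && learning_rate <= 0)
    stop_config("learning_rate must be > 0 for adam")
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), optimizer = optimizer,
                 learning_rate = learning_rate,
                 class_weighting = isTRUE(class_weighting),
                 aug_rotate = aug_rotate, aug_translate = aug_translate,
                 clip_norm = clip_norm, lr_decay = lr_decay,
                 init_from = init_from, seed = as.integer(seed)),
            class = "train_config")
}

# Rotation/translation augmentation for matrices or (H, W, C) arrays.
augment_image <- function(img, ang, shx, shy) {
  if (is.matrix(img)) return(cpp_affine_sample(img, ang, shx, shy))
  d <- dim(img)
  if (length(d) == 3L) {
    out <- array(0, d)
    for (ch in seq_len(d[3]))
      out[, , ch] <- cpp_affine_sample(matrix(img[, , ch], d[1], d[2]),
                                       ang, shx, shy)
    return(out)
  }
  stop_data("cannot augment an object with %d dimensions", length(d))
}

# Normalise the accepted dataset forms to list(images = list, labels = int).
as_dataset <- function(x) {
  if (is.list(x) && !is.null(x$images) && !is.null(x$labels))
    return(list(images = x$images, labels = as.integer(x$labels)))
  if (is.list(x) && length(x) > 0L && !is.null(x[[1]]$image))
    return(list(images = lapply(x, `[[`, "image"),
                labels = vapply(x, function(s) as.integer(s$label), 1L)))
  stop_data("dataset must be a list of samples or list(images=, labels=)")
}

copy_params_from <- function(model, ref) {
  pm <- get_params(model)
  pr <- get_params(ref)
  check <- function(a, b, path) {
    if (is.numeric(a)) {
      if (!is.numeric(b) || !identical(dim(a), dim(b)) || length(a) != length(b))
        stop_data("checkpoint shape mismatch at %s", path)
      return(invisible())
    }
    if (length(a) != length(b))
      stop_data("checkpoint structure mismatch at %s", path)
    for (i in seq_along(a))
      if (!is.null(a[[i]])) check(a[[i]], b[[i]], paste0(path, "/", i))
  }
  check(pm, pr, "params")
  model <- set_params(model, pr)
  copy_stats <- function(layers, ref_layers) {
    for (i in seq_along(layers)) {
      if (layers[[i]]$type == "ebn") {
        layers[[i]]$rmean <- ref_layers[[i]]$rmean
        layers[[i]]$rvar <- ref_layers[[i]]$rvar
      } else if (layers[[i]]$type == "dense_unit") {
        layers[[i]]$sub <- copy_stats(layers[[i]]$sub, ref_layers[[i]]$sub)
      }
    }
    layers
  }
  model$layers <- copy_stats(model$layers, ref$layers)
  model
}

#' Train a classifier
#'
#' Runs the configured number of epochs of minibatch training with
#' (class-weighted) binary cross-entropy, per-epoch validation F1, and
#' returns the checkpoint of the epoch with maximal validation F1 (ties go
#' to the earlier epoch). With `config$init_from` set, weights are copied
#' from that checkpoint before training (warm start from a model trained on
#' a related condition).
#'
#' @param model untrained `sal_model`.
#' @param train_data,val_data datasets: a list of phantom samples or
#'   `list(images = <list of matrices>, labels = <0/1 vector>)`.
#' @param config a [train_config()].
#' @return `list(model = selected TrainedModel, log = TrainingLog data.frame)`.
#' @export
train <- function(model, train_data, val_data, config = train_config()) {
  tr <- as_dataset(train_data)
  va <- as_dataset(val_data)
  if (length(tr$images) == 0L || length(va$images) == 0L)
    stop_data("training and validation sets must be non-empty")
  w <- c(1, 1)
  if (config$class_weighting) w <- class_weights(tr$labels)
  if (!is.null(config$init_from))
    model <- copy_params_from(model, config$init_from)
  if (isTRUE(model$center_on) && is.null(model$center))
    model$center <- compute_center(model, tr$images)
  has_ebn <- function(layers) any(vapply(layers, function(l)
    l$type == "ebn" || (l$type == "dense_unit" && has_ebn(l$sub)), TRUE))
  track_stats <- has_ebn(model$layers)

  opt <- make_optimizer(config$optimizer, config$learning_rate)
  n <- length(tr$images)
  side <- model$input_spec[1]
  log <- data.frame(epoch = integer(), loss = numeric(), val_f1 = numeric(),
                    selected = logical())
  best <- list(f1 = -Inf, model = NULL, epoch = NA_integer_)

  with_seed(config$seed, {
    if (track_stats) {
      # warm up the running normalisation statistics with one plain forward
      # sweep so epoch 1 trains against stable statistics
      for (i in seq_len(n)) {
        fw <- model_forward(model, prepare_input(model, tr$images[[i]]))
        model <- model_update_stats(model, fw$bb$caches)
      }
    }
    for (ep in seq_len(config$epochs)) {
      if (!is.null(config$lr_decay)) {
        opt$state$scale <- if (length(config$lr_decay) > 1L)
          config$lr_decay[(ep - 1L) %% length(config$lr_decay) + 1L]
        else config$lr_decay^(ep - 1)
      }
      ord <- sample.int(n)
      losses <- numeric(0)
      for (start in seq(1L, n, by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1L, n)]
        gacc <- NULL
        bl <- 0
        for (i in idx) {
          img <- tr$images[[i]]
          if (config$aug_rotate > 0 || config$aug_translate > 0) {
            ang <- runif(1, -config$aug_rotate, config$aug_rotate)
            sh <- runif(2, -config$aug_translate, config$aug_translate) *
              dim(img)[1]
            img <- augment_image(img, ang, sh[1], sh[2])
          }
          x <- prepare_input(model, img)
          y <- tr$labels[i]
          fw <- model_forward(model, x)
          bl <- bl + weighted_bce(y, fw$prob, w)
          g_logit <- w[y + 1L] * (fw$prob - y) / length(idx)
          g <- model_backward(model, fw, g_logit)
          gacc <- if (is.null(gacc)) g else tree_add(gacc, g)
          if (track_stats)
            model <- model_update_stats(model, fw$bb$caches)
        }
        losses <- c(losses, bl / length(idx))
        if (!is.null(config$clip_norm) && config$clip_norm > 0) {
          gn <- sqrt(sum(unlist(gacc)^2))
          if (gn > config$clip_norm)
            gacc <- tree_leaves_apply(gacc, gacc, function(g, .)
              g * config$clip_norm / gn)
        }
        params <- opt$step(get_params(model), gacc)
        model <- set_params(model, params)
      }
      val_p <- vapply(va$images, function(im) predict_prob(model, im), 1.0)
      f1 <- f1_score(val_p, va$labels)
      log <- rbind(log, data.frame(epoch = ep, loss = mean(losses),
                                   val_f1 = f1, selected = FALSE))
      if (f1 > best$f1) best <- list(f1 = f1, model = model, epoch = ep)
    }
  })
  log$selected <- log$epoch == best$epoch
  model <- best$model
  model$trained <- TRUE
  model$meta$selected_epoch <- best$epoch
  model$meta$val_f1 <- best$f1
  model$meta$fingerprint <- model_fingerprint(model)
  list(model = model, log = log)
}

#' Save / load a model checkpoint with a JSON sidecar
#' @param model trained `sal_model`.
#' @param path file path for the serialized checkpoint; `<path>.json` gets
#'   the sidecar metadata.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(model, path)
  side <- list(architecture_id = model$architecture_id,
               input_spec = model$input_spec,
               feature_dim = model$feature_dim,
               seed = model$seed,
               selected_epoch = model$meta$selected_epoch,
               attention = !is.null(model$head),
               fingerprint = model$meta$fingerprint)
  if (!is.null(model$meta$saliency_source))
    side$saliency_source <- model$meta$saliency_source
  if (!is.null(model$head))
    side$taps <- lapply(model$head$levels, function(l) l$in_shape)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop_data("checkpoint not found: %s", path)
  readRDS(path)
}
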
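# Synthetic phantom radiographs. Each image is one of a small set of smooth
# elliptical "thorax" archetypes (body habitus / exposure variants) with
# per-sample affine jitter, a low-frequency multiplicative field and pixel
# noise; positive samples additionally carry a spatially confined lesion
# whose contrast and extent grow with a continuous severity in (0, 1].
# Global appearance is dominated by the archetype, not the lesion, which
# recreates the clinical trap that the overall most similar image is not the
# most similar image in terms of disease.

#' Phantom generator configuration
#'
#' @param image_size pixels per (square) side, >= 32.
#' @param background_modes number of global-appearance archetypes.
#' @param background_noise_sd grayscale noise standard deviation.
#' @param lesion_region fractional bounding box `c(x0, y0, x1, y1)` strictly
#'   inside the image where lesions occur (y grows downward; the default is
#'   a basal band).
#' @param severity_range closed severity interval; the minimum must be 0
#'   (negatives have severity exactly 0).
#' @param lesion_contrast_at_max grayscale offset of the lesion at severity 1.
#' @param class_balance fraction of positive (diseased) samples, in (0, 1).
#' @param condition `"effusion"` (basal gradient wedge) or `"pneumonia"`
#'   (1-3 soft blobs).
#' @param seed integer master seed.
#' @export
phantom_config <- function(image_size = 96L, background_modes = 6L,
                           background_noise_sd = 0.02,
                           lesion_region = c(0.2, 0.55, 0.8, 0.92),
                           severity_range = c(0, 1),
                           lesion_contrast_at_max = 0.4,
                           class_balance = 0.5,
                           condition = c("effusion", "pneumonia"),
                           seed = 1L) {
  condition <- match.arg(condition)
  if (!is.numeric(image_size) || image_size < 32)
    stop_config("invalid config: image_size must be >= 32")
  if (background_modes < 1) stop_config("invalid config: background_modes must be >= 1")
  if (background_noise_sd < 0) stop_config("invalid config: background_noise_sd must be >= 0")
  if (length(lesion_region) != 4 || any(lesion_region <= 0) ||
      any(lesion_region >= 1) || lesion_region[1] >= lesion_region[3] ||
      lesion_region[2] >= lesion_region[4])
    stop_config("invalid config: lesion_region must be c(x0, y0, x1, y1) strictly inside (0, 1)")
  if (length(severity_range) != 2 || severity_range[1] != 0 ||
      severity_range[2] <= 0 || severity_range[2] > 1)
    stop_config("invalid config: severity_range must be c(0, max] with max in (0, 1]")
  if (lesion_contrast_at_max <= 0 || lesion_contrast_at_max > 1)
    stop_config("invalid config: lesion_contrast_at_max must be in (0, 1]")
  if (class_balance <= 0 || class_balance >= 1)
    stop_config("invalid config: class_balance must be in (0, 1)")
  structure(list(image_size = as.integer(image_size),
                 background_modes = as.integer(background_modes),
                 background_noise_sd = background_noise_sd,
                 lesion_region = as.numeric(lesion_region),
                 severity_range = as.numeric(severity_range),
                 lesion_contrast_at_max = lesion_contrast_at_max,
                 class_balance = class_balance, condition = condition,
                 seed = as.integer(seed)),
            class = "phantom_config")
}

# Fixed archetype parameters, a deterministic function of the mode index.
background_archetype <- function(mode) {
  with_seed(derive_seed(97L, mode), list(
    gain = runif(1, 0.6, 1.0),
    ax = runif(1, 0.3, 0.44),
    ay = runif(1, 0.36, 0.5),
    cx = runif(1, 0.46, 0.54),
    cy = runif(1, 0.48, 0.56),
    lung_dark = runif(1, 0.2, 0.45),
    lung_sep = runif(1, 0.16, 0.24),
    lung_ax = runif(1, 0.10, 0.15),
    lung_ay = runif(1, 0.18, 0.26)))
}

soft_ellipse <- function(u, v, cx, cy, ax, ay, softness = 0.08) {
  e <- ((u - cx) / ax)^2 + ((v - cy) / ay)^2
  1 / (1 + exp((e - 1) / softness))
}

render_background <- function(config, mode) {
  S <- config$image_size
  p <- background_archetype(mode)
  v <- matrix(seq(0, 1, length.out = S), S, S)         # row fraction
  u <- t(v)                                            # column fraction
  body <- soft_ellipse(u, v, p$cx, p$cy, p$ax, p$ay)
  lungs <- soft_ellipse(u, v, p$cx - p$lung_sep, p$cy - 0.08,
                        p$lung_ax, p$lung_ay, 0.1) +
           soft_ellipse(u, v, p$cx + p$lung_sep, p$cy - 0.08,
                        p$lung_ax, p$lung_ay, 0.1)
  0.1 + p$gain * 0.75 * body - p$lung_dark * body * pmin(lungs, 1)
}

render_lesion <- function(config, severity) {
  S <- config$image_size
  r <- config$lesion_region
  v <- matrix(seq(0, 1, length.out = S), S, S)
  u <- t(v)
  amp <- config$lesion_contrast_at_max * severity
  if (config$condition == "effusion") {
    # basal wedge: fills the region bottom-up as severity grows, with a soft
    # top edge and a smooth horizontal taper
    top <- r[4] - severity * (r[4] - r[2])
    ramp <- pmin(pmax((v - top) / pmax(r[4] - top, 1e-9), 0), 1)
    ramp[v > r[4]] <- 0
    taper <- sin(pi * pmin(pmax((u - r[1]) / (r[3] - r[1]), 0), 1))
    taper[u < r[1] | u > r[3]] <- 0
    amp * ramp * taper
  } else {
    nb <- 1L + (severity > 0.4) + (severity > 0.75)
    les <- matrix(0, S, S)
    for (b in seq_len(nb)) {
      cx <- runif(1, r[1] + 0.08, r[3] - 0.08)
      cy <- runif(1, r[2] + 0.08, r[4] - 0.08)
      sg <- 0.04 + 0.05 * severity
      les <- les + exp(-(((u - cx)^2 + (v - cy)^2) / (2 * sg^2)))
    }
    amp * pmin(les, 1)
  }
}

# Deterministic given (config, index, label): everything sample-specific is
# drawn from a stream derived from the master seed and the sample index.
render_phantom <- function(config, index, label) {
  S <- config$image_size
  with_seed(derive_seed(config$seed, index), {
    mode <- sample.int(config$background_modes, 1L)
    # positives sit above a detectability floor: severity encodes clinically
    # visible disease extent, never a sub-noise lesion. The draw is taken
    # unconditionally so the per-sample stream is label-invariant.
    sev_draw <- runif(1, max(0.15, config$severity_range[1]),
                      config$severity_range[2])
    severity <- if (label == 1L) sev_draw else 0
    img <- render_background(config, mode)
    ang <- runif(1, -4, 4)
    sh <- runif(2, -0.02, 0.02) * S
    img <- cpp_affine_sample(img, ang, sh[1], sh[2])
    # low-frequency multiplicative field (exposure inhomogeneity)
    fx <- runif(1, 0.5, 1.5); fy <- runif(1, 0.5, 1.5)
    ph <- runif(2, 0, 2 * pi)
    v <- matrix(seq(0, 1, length.out = S), S, S); u <- t(v)
    field <- 1 + 0.06 * sin(2 * pi * fx * u + ph[1]) *
                 sin(2 * pi * fy * v + ph[2])
    img <- img * field
    if (label == 1L) img <- img + render_lesion(config, severity)
    img <- img + matrix(rnorm(S * S, sd = config$background_noise_sd), S, S)
    img <- pmin(pmax(img, 0), 1)
    img <- round(img * 255) / 255   # 8-bit grid, lossless PNG round trips
    structure(list(sample_id = sprintf("s%05d", index), image = img,
                   label = as.integer(label), severity = severity,
                   background_mode = mode),
              class = "phantom_sample")
  })
}

#' Generate a phantom dataset
#'
#' Produces `n` phantom samples with exactly `round(n * class_balance)`
#' positives. Everything is deterministic given the configuration: the same
#' config and `n` reproduce bit-identical images.
#'
#' @param config a [phantom_config()].
#' @param n number of samples (>= 2).
#' @return list of `phantom_sample` objects (fields `sample_id`, `image`,
#'   `label`, `severity`, `background_mode`).
#' @export
generate_dataset <- function(config, n) {
  if (!inherits(config, "phantom_config"))
    stop_config("config must be a phantom_config")
  if (n < 2) stop_config("invalid config: n must be >= 2")
  n_pos <- round(n * config$class_balance)
  labels <- integer(n)
  pos_idx <- with_seed(derive_seed(config$seed, 0L), sample.int(n, n_pos))
  labels[pos_idx] <- 1L
  lapply(seq_len(n), function(i) render_phantom(config, i, labels[i]))
}

#' Ground-truth severity ranking of a catalogue
#'
#' Orders catalogue samples by increasing absolute severity difference to
#' the query; exact ties are broken by putting same-label items first, then
#' by ascending sample id.
#'
#' @param query a `phantom_sample`.
#' @param catalogue list of `phantom_sample`.
#' @return character vector of sample ids, rank 1 first.
#' @export
ground_truth_ranking <- function(query, catalogue) {
  if (length(catalogue) == 0L) stop_data("catalogue must be non-empty")
  ids <- vapply(catalogue, `[[`, "", "sample_id")
  sev <- vapply(catalogue, `[[`, 1.0, "severity")
  lab <- vapply(catalogue, function(s) as.integer(s$label), 1L)
  dsev <- abs(sev - query$severity)
  mismatch <- as.integer(lab != query$label)
  unname(ids[order(dsev, mismatch, ids)])
}

#' Query/catalogue splits with severity ground truth
#'
#' Draws `n_queries` distinct query images, each paired with a catalogue of
#' `p` images sampled from the remaining pool so that the catalogue class
#' proportions match the pool proportion to within one image. Catalogue ids
#' are stored already ordered by the ground-truth severity ranking (rank 1
#' first). A query never appears in its own catalogue; catalogues of
#' different splits may overlap.
#'
#' @param samples list of `phantom_sample`.
#' @param n_queries number of splits.
#' @param p catalogue size (default 10).
#' @param seed integer seed.
#' @return list of splits: `list(split_id, query_id, catalogue_ids, p)`.
#' @export
make_splits <- function(samples, n_queries, p = 10L, seed = 1L) {
  n <- length(samples)
  if (n < p + 1L || n < n_queries)
    stop_data("not enough samples (%d) for %d queries with catalogues of %d",
              n, n_queries, p)
  ids <- vapply(samples, `[[`, "", "sample_id")
  names(samples) <- ids
  lab <- vapply(samples, function(s) as.integer(s$label), 1L)
  n_pos_cat <- round(p * mean(lab == 1L))
  q_idx <- with_seed(derive_seed(seed, 1L), sample.int(n, n_queries))
  lapply(seq_len(n_queries), function(k) {
    qid <- ids[q_idx[k]]
    pool <- setdiff(ids, qid)
    pos <- pool[lab[pool] == 1L]
    neg <- pool[lab[pool] == 0L]
    if (length(pos) < n_pos_cat || length(neg) < p - n_pos_cat)
      stop_data("not enough samples of each class for catalogue of %d", p)
    cat_ids <- with_seed(derive_seed(seed, 1000L + k), {
      c(sample(pos, n_pos_cat), sample(neg, p - n_pos_cat))
    })
    ordered <- ground_truth_ranking(samples[[qid]], samples[cat_ids])
    structure(list(split_id = sprintf("split%02d", k), query_id = qid,
                   catalogue_ids = ordered, p = as.integer(p)),
              class = "qc_split")
  })
}

# ---- manifest I/O ----------------------------------------------------------

#' Write / read a dataset manifest
#'
#' `write_manifest()` stores images as 8-bit grayscale PNG under
#' `dir/images/`, a CSV manifest (`sample_id,filename,label,severity,
#' background_mode`) and the splits as JSON. `read_manifest()` restores them
#' and validates referential integrity. Round-tripping is exact: images are
#' generated on the 8-bit grid.
#'
#' @param samples list of `phantom_sample`.
#' @param splits list of splits (may be empty).
#' @param dir target directory (created if needed).
#' @export
write_manifest <- function(samples, splits, dir) {
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  df <- data.frame(
    sample_id = vapply(samples, `[[`, "", "sample_id"),
    filename = vapply(samples, function(s)
      file.path("images", paste0(s$sample_id, ".png")), ""),
    label = vapply(samples, function(s) as.integer(s$label), 1L),
    severity = vapply(samples, `[[`, 1.0, "severity"),
    background_mode = vapply(samples, function(s)
      as.integer(s$background_mode), 1L),
    stringsAsFactors = FALSE)
  if (nrow(df) == 0L)
    df <- data.frame(sample_id = character(), filename = character(),
                     label = integer(), severity = numeric(),
                     background_mode = integer())
  for (s in samples)
    png::writePNG(s$image, file.path(dir, "images",
                                     paste0(s$sample_id, ".png")))
  write.csv(df, file.path(dir, "manifest.csv"), row.names = FALSE)
  jsonlite::write_json(
    lapply(splits, function(sp) list(split_id = sp$split_id,
                                     query_id = sp$query_id,
                                     catalogue_ids = sp$catalogue_ids,
                                     p = sp$p)),
    file.path(dir, "splits.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(dir) {
  mf <- file.path(dir, "manifest.csv")
  if (!file.exists(mf)) stop_data("no manifest.csv in %s", dir)
  df <- read.csv(mf, stringsAsFactors = FALSE, colClasses = c(
    sample_id = "character", filename = "character"))
  missing <- df$sample_id[!file.exists(file.path(dir, df$filename))]
  if (length(missing) > 0L)
    stop_data("missing image files for: %s", paste(missing, collapse = ", "))
  samples <- lapply(seq_len(nrow(df)), function(i) {
    img <- png::readPNG(file.path(dir, df$filename[i]))
    if (length(dim(img)) == 3L) img <- img[, , 1L]
    structure(list(sample_id = df$sample_id[i], image = img,
                   label = as.integer(df$label[i]),
                   severity = df$severity[i],
                   background_mode = as.integer(df$background_mode[i])),
              class = "phantom_sample")
  })
  names(samples) <- df$sample_id
  splits <- list()
  sf <- file.path(dir, "splits.json")
  if (file.exists(sf)) {
    raw <- jsonlite::read_json(sf)
    splits <- lapply(raw, function(sp) {
      cat_ids <- unlist(sp$catalogue_ids)
      unknown <- setdiff(c(sp$query_id, cat_ids), df$sample_id)
      if (length(unknown) > 0L)
        stop_data("split %s references unknown sample ids: %s", sp$split_id,
                  paste(unknown, collapse = ", "))
      structure(list(split_id = sp$split_id, query_id = sp$query_id,
                     catalogue_ids = cat_ids, p = as.integer(sp$p)),
                class = "qc_split")
    })
  }
  list(samples = samples, splits = splits)
}
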
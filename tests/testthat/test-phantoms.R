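test_that("configuration validation names the offending field", {
  expect_error(phantom_config(image_size = 16), "image_size")
  expect_error(phantom_config(class_balance = 1), "class_balance")
  expect_error(phantom_config(class_balance = 0), "class_balance")
  expect_error(phantom_config(lesion_region = c(0, 0.5, 0.8, 0.9)),
               "lesion_region")
  expect_error(phantom_config(lesion_region = c(0.5, 0.5, 0.2, 0.9)),
               "lesion_region")
  expect_error(phantom_config(severity_range = c(0.2, 1)), "severity_range")
  expect_error(generate_dataset(phantom_config(), 1), "n must be")
})

test_that("generation is deterministic and class balance is exact", {
  cfg <- phantom_config(image_size = 48, class_balance = 0.3, seed = 9)
  a <- generate_dataset(cfg, 20)
  b <- generate_dataset(cfg, 20)
  expect_identical(lapply(a, `[[`, "image"), lapply(b, `[[`, "image"))
  labs <- vapply(a, `[[`, 1L, "label")
  expect_identical(sum(labs), as.integer(round(20 * 0.3)))
  # label <=> severity > 0, images clipped to [0, 1]
  for (s in a) {
    expect_identical(s$label == 1L, s$severity > 0)
    expect_true(all(s$image >= 0 & s$image <= 1))
  }
})

test_that("negative phantoms carry no lesion signal", {
  cfg <- phantom_config(image_size = 48, seed = 5)
  ns <- asNamespace("saliret")
  # a negative equals the rendered sample with label 0: rendering the same
  # index with label 1 differs only inside the lesion region
  neg <- ns$render_phantom(cfg, 3L, 0L)
  expect_identical(neg$severity, 0)
  pos <- ns$render_phantom(cfg, 3L, 1L)
  r <- cfg$lesion_region
  S <- cfg$image_size
  outside <- matrix(TRUE, S, S)
  rows <- seq(floor(r[2] * S), ceiling(r[4] * S))
  cols <- seq(floor(r[1] * S), ceiling(r[3] * S))
  outside[rows, cols] <- FALSE
  expect_lt(max(abs(pos$image[outside] - neg$image[outside])), 3 / 255)
  expect_gt(mean(pos$image[!outside]) - mean(neg$image[!outside]), 0.01)
})

test_that("mean lesion contrast increases strictly with severity", {
  cfg <- phantom_config()
  ns <- asNamespace("saliret")
  sev_grid <- seq(0.1, 1, by = 0.1)
  m <- vapply(sev_grid, function(s) mean(ns$render_lesion(cfg, s)), 1.0)
  expect_true(all(diff(m) > 0))
  # spot check the spec-style triple on full rendered images, one background
  r <- cfg$lesion_region
  S <- cfg$image_size
  rows <- seq(floor(r[2] * S), ceiling(r[4] * S))
  cols <- seq(floor(r[1] * S), ceiling(r[3] * S))
  bg <- ns$render_background(cfg, 2L)
  region_mean <- function(s) mean((bg + ns$render_lesion(cfg, s))[rows, cols])
  v <- vapply(c(0.2, 0.5, 0.9), region_mean, 1.0)
  expect_true(all(diff(v) > 0))
})

test_that("ground-truth ranking follows |severity difference| with id ties", {
  mk <- function(id, sev, lab = as.integer(sev > 0))
    structure(list(sample_id = id, image = NULL, label = lab, severity = sev,
                   background_mode = 1L), class = "phantom_sample")
  q <- mk("q", 0.85)
  expect_identical(ground_truth_ranking(q, list(mk("A", 0.9), mk("B", 0.1),
                                                mk("C", 0.5))),
                   c("A", "C", "B"))
  qn <- mk("q", 0, 0L)
  expect_identical(ground_truth_ranking(qn, list(mk("p", 0.7), mk("n", 0, 0L))),
                   c("n", "p"))
  # exact severity tie: same-label first, then ascending id
  qt <- mk("q", 0.5)
  expect_identical(
    ground_truth_ranking(qt, list(mk("b", 0.5), mk("a", 0.5))), c("a", "b"))
  expect_identical(
    ground_truth_ranking(qn, list(mk("z", 0.5), mk("y", 0.5, 0L))),
    c("y", "z"))
  expect_error(ground_truth_ranking(q, list()), "non-empty")
})

test_that("splits respect protocol sizes, proportions and determinism", {
  samples <- small_phantoms(60, seed = 3)
  sp10 <- make_splits(samples, n_queries = 10, p = 10, seed = 2)
  expect_length(sp10, 10L)
  for (sp in sp10) {
    expect_length(sp$catalogue_ids, 10L)
    expect_false(sp$query_id %in% sp$catalogue_ids)
    expect_false(anyDuplicated(sp$catalogue_ids) > 0)
  }
  sp5 <- make_splits(samples, n_queries = 5, p = 10, seed = 2)
  expect_length(sp5, 5L)
  expect_identical(make_splits(samples, 10, 10, seed = 2), sp10)
  # class proportions within one image of the pool proportion
  labs <- vapply(samples, `[[`, 1L, "label")
  names(labs) <- vapply(samples, `[[`, "", "sample_id")
  pool_frac <- mean(labs == 1L)
  for (sp in sp10) {
    npos <- sum(labs[sp$catalogue_ids] == 1L)
    expect_lte(abs(npos - 10 * pool_frac), 1)
  }
  # catalogue is stored in ground-truth order
  names(samples) <- names(labs)
  for (sp in sp10[1:3]) {
    expect_identical(sp$catalogue_ids,
                     ground_truth_ranking(samples[[sp$query_id]],
                                          samples[sp$catalogue_ids]))
  }
  expect_error(make_splits(samples[1:6], 2, p = 10), "not enough")
})

test_that("manifests round-trip exactly and validate integrity", {
  samples <- small_phantoms(20, seed = 8)
  splits <- make_splits(samples, 2, p = 6, seed = 1)
  dir <- withr::local_tempdir()
  write_manifest(samples, splits, dir)
  back <- read_manifest(dir)
  expect_equal(vapply(back$samples, `[[`, 1.0, "severity"),
               stats::setNames(vapply(samples, `[[`, 1.0, "severity"),
                               vapply(samples, `[[`, "", "sample_id")),
               tolerance = 1e-12)
  expect_identical(unname(vapply(back$samples, `[[`, 1L, "label")),
                   vapply(samples, `[[`, 1L, "label"))
  for (i in seq_along(samples))
    expect_equal(back$samples[[i]]$image, samples[[i]]$image,
                 tolerance = 1e-12)
  expect_identical(lapply(back$splits, `[[`, "catalogue_ids"),
                   lapply(splits, `[[`, "catalogue_ids"))

  # unknown id in a split is rejected
  bad <- splits
  bad[[1]]$catalogue_ids[1] <- "s99999"
  dir2 <- withr::local_tempdir()
  write_manifest(samples, bad, dir2)
  expect_error(read_manifest(dir2), "s99999")

  # missing image file is reported with the id
  file.remove(file.path(dir, "images", paste0(samples[[1]]$sample_id, ".png")))
  expect_error(read_manifest(dir), samples[[1]]$sample_id)

  # empty dataset: valid, empty manifest
  dir3 <- withr::local_tempdir()
  write_manifest(list(), list(), dir3)
  empty <- read_manifest(dir3)
  expect_length(empty$samples, 0L)
  expect_length(empty$splits, 0L)
})

test_that("whole-image similarity is dominated by background, not disease", {
  # the premise of disease-targeted retrieval: the globally most similar
  # catalogue image shares the query's anatomy archetype more often than it
  # is the true severity match
  cfg <- phantom_config(seed = 21)
  samples <- generate_dataset(cfg, 130)
  names(samples) <- vapply(samples, `[[`, "", "sample_id")
  splits <- make_splits(samples, n_queries = 10, p = 10, seed = 4)
  mode_hits <- 0L
  sev_hits <- 0L
  for (sp in splits) {
    q <- samples[[sp$query_id]]
    sims <- vapply(sp$catalogue_ids,
                   function(id) ssim(q$image, samples[[id]]$image), 1.0)
    top <- sp$catalogue_ids[which.max(sims)]
    if (samples[[top]]$background_mode == q$background_mode)
      mode_hits <- mode_hits + 1L
    if (top == sp$catalogue_ids[1]) sev_hits <- sev_hits + 1L
  }
  expect_gt(mode_hits, sev_hits)
})

test_that("the ground-truth pipeline scores nDCG = 1 on every split", {
  samples <- small_phantoms(80, seed = 13)
  splits <- make_splits(samples, 10, p = 10, seed = 6)
  for (sp in splits)
    expect_identical(ndcg(sp$catalogue_ids, sp$catalogue_ids), 1)
})
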
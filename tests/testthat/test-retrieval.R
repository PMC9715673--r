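test_that("SSIM matches closed forms and is symmetric", {
  a <- matrix(runif(48 * 48), 48, 48)
  expect_equal(ssim(a, a), 1, tolerance = 1e-12)
  # zero-variance images: the structure term is 1 and the luminance term has
  # the closed form (2 m1 m2 + C1) / (m1^2 + m2^2 + C1)
  c1 <- matrix(0.5, 48, 48)
  c2 <- matrix(0.25, 48, 48)
  expected <- (2 * 0.5 * 0.25 + 1e-4) / (0.5^2 + 0.25^2 + 1e-4)
  expect_equal(ssim(c1, c2), expected, tolerance = 1e-9)
  set.seed(5)
  for (i in 1:10) {
    x <- matrix(runif(20 * 20), 20, 20)
    y <- matrix(runif(20 * 20), 20, 20)
    expect_equal(ssim(x, y), ssim(y, x), tolerance = 1e-12)
  }
  expect_error(ssim(a, matrix(0, 20, 20)), "identical dimensions")
})

test_that("pairwise distance is Euclidean and obeys the triangle inequality", {
  expect_identical(pairwise_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_identical(pairwise_distance(c(0, 0), c(3, 4)), 5)
  expect_error(pairwise_distance(1:3, 1:4), "lengths")
  set.seed(17)
  for (i in 1:100) {
    a <- rnorm(8); b <- rnorm(8); ch <- rnorm(8)
    expect_lte(pairwise_distance(a, ch),
               pairwise_distance(a, b) + pairwise_distance(b, ch) + 1e-12)
  }
})

make_retrieval_setup <- function(p = 4, seed = 33) {
  samples <- small_phantoms(p + 4, seed = seed)
  names(samples) <- vapply(samples, `[[`, "", "sample_id")
  split <- make_splits(samples, 1, p = p, seed = 2)[[1]]
  images <- lapply(samples, `[[`, "image")
  models <- list(cnn = build_backbone("tiny", input_spec = c(32, 32, 1),
                                      seed = 1),
                 ig = build_backbone("tiny", input_spec = c(32, 32, 1),
                                     seed = 2),
                 att = build_attention_model("tiny",
                                             input_spec = c(32, 32, 1)))
  models$cnn$meta$fingerprint <- "cnnfp"
  list(samples = samples, split = split, images = images, models = models)
}

test_that("every method returns an ordered catalogue permutation", {
  su <- make_retrieval_setup()
  cache <- new.env(parent = emptyenv())
  for (mid in c("ssim", "cnn", "cnn_ig", "ig", "att")) {
    r <- rank_catalogue(su$split, mid, su$images, su$models,
                        saliency_cache = cache)
    expect_setequal(r$ranking, su$split$catalogue_ids)
    if (mid == "ssim") expect_true(all(diff(r$scores) <= 1e-12))
    else expect_true(all(diff(r$scores) >= -1e-12))
  }
  expect_gt(length(ls(cache)), 0L)
})

test_that("a query identical to a catalogue image is retrieved first", {
  su <- make_retrieval_setup()
  images <- su$images
  images[[su$split$query_id]] <- images[[su$split$catalogue_ids[3]]]
  for (mid in c("ssim", "cnn", "att")) {
    r <- rank_catalogue(su$split, mid, images, su$models)
    expect_identical(r$ranking[1], su$split$catalogue_ids[3])
    if (mid == "ssim") expect_equal(unname(r$scores[1]), 1, tolerance = 1e-12)
    else expect_equal(unname(r$scores[1]), 0, tolerance = 1e-9)
  }
})

test_that("exact ties are broken by ascending sample id", {
  su <- make_retrieval_setup()
  images <- su$images
  dup <- sort(su$split$catalogue_ids[1:2])
  images[[dup[2]]] <- images[[dup[1]]]
  for (mid in c("ssim", "cnn")) {
    r <- rank_catalogue(su$split, mid, images, su$models)
    pos <- match(dup, r$ranking)
    expect_identical(diff(pos), 1L)
  }
  # degenerate catalogue of one
  one <- su$split
  one$catalogue_ids <- one$catalogue_ids[1]
  one$p <- 1L
  for (mid in c("ssim", "cnn", "att")) {
    r <- rank_catalogue(one, mid, su$images, su$models)
    expect_identical(r$ranking, one$catalogue_ids)
  }
})

test_that("missing checkpoints are reported with the method id", {
  su <- make_retrieval_setup()
  expect_error(rank_catalogue(su$split, "ig", su$images,
                              su$models["cnn"]), "ig")
  expect_error(rank_catalogue(su$split, "att", su$images, list()), "att")
  expect_error(rank_catalogue(su$split, "warp", su$images, su$models),
               "method_id|arg")
  missing_imgs <- su$images
  missing_imgs[[su$split$catalogue_ids[1]]] <- NULL
  expect_error(rank_catalogue(su$split, "ssim", missing_imgs, su$models),
               su$split$catalogue_ids[1])
})

test_that("retrieval results export one CSV row per rank", {
  su <- make_retrieval_setup()
  r1 <- rank_catalogue(su$split, "ssim", su$images)
  r2 <- rank_catalogue(su$split, "cnn", su$images, su$models)
  path <- withr::local_tempfile(fileext = ".csv")
  write_retrieval_results(list(r1, r2), path)
  df <- read.csv(path)
  expect_identical(nrow(df), 2L * su$split$p)
  expect_identical(unique(df$method_id), c("ssim", "cnn"))
  expect_identical(df$rank[df$method_id == "cnn"], seq_len(su$split$p))
})
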
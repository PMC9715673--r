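test_that("the relevance scheme is linear from 5.5 to 1 in steps of 0.5", {
  ids <- sprintf("c%02d", 1:10)
  rel <- assign_relevance(ids)
  expect_equal(unname(rel[1]), 5.5, tolerance = 1e-12)
  expect_equal(unname(rel[10]), 1, tolerance = 1e-12)
  expect_equal(unique(round(-diff(rel), 12)), 0.5)
  # generalised to arbitrary catalogue sizes
  rel4 <- assign_relevance(sprintf("c%d", 1:4))
  expect_equal(unname(rel4[1]), 2.5, tolerance = 1e-12)
  expect_error(assign_relevance(c("a", "a", "b")), "duplicate")
  expect_error(assign_relevance(ids, relevance_scheme(p = 5)), "expects 5")
})

test_that("DCG matches direct evaluation and rewards correct ordering", {
  ids <- sprintf("c%02d", 1:10)
  rel <- assign_relevance(ids)
  expect_equal(dcg(rev(ids), rel, p_eval = 1), (2^1 - 1) / log2(2),
               tolerance = 1e-12)
  expect_equal(dcg(ids, rel, p_eval = 1), 2^5.5 - 1, tolerance = 1e-12)
  expect_equal(2^5.5 - 1, 44.254834, tolerance = 1e-6)
  expect_error(dcg(ids, rel, p_eval = 11), "exceeds")
  expect_error(dcg(c("zz", ids[-1]), rel), "zz")
  # moving a higher-relevance item earlier strictly increases DCG
  set.seed(3)
  for (i in 1:20) {
    perm <- sample(ids)
    j <- sample(9, 1)
    if (rel[perm[j]] >= rel[perm[j + 1]]) {
      perm2 <- perm
      perm2[c(j, j + 1)] <- perm2[c(j + 1, j)]  # now worse first
      if (rel[perm[j]] > rel[perm[j + 1]])
        expect_gt(dcg(perm, rel), dcg(perm2, rel))
    }
  }
})

test_that("nDCG equals the exhaustive brute-force oracle", {
  ids <- letters[1:5]
  perms <- all_perms(ids)
  expect_length(perms, 120L)
  for (perm in perms) {
    expect_equal(ndcg(perm, ids), brute_ndcg(perm, ids), tolerance = 1e-12)
    expect_equal(ndcg(perm, ids, p_eval = 3), brute_ndcg(perm, ids, 3),
                 tolerance = 1e-12)
  }
  expect_identical(ndcg(ids, ids), 1)
  expect_identical(ndcg(ids, ids, p_eval = 3), 1)
  # two-item catalogue reversed: closed form
  two <- c("x", "y")
  expected <- (1 + (2^1.5 - 1) / log2(3)) / ((2^1.5 - 1) + 1 / log2(3))
  expect_equal(ndcg(rev(two), two), expected, tolerance = 1e-12)
  expect_equal(expected, 0.8757, tolerance = 1e-4)
  expect_error(ndcg(c("a", "b"), c("a", "c")), "permutations")
})

test_that("nDCG is bounded in (0, 1] and 1 only at the ideal prefix", {
  ids <- letters[1:5]
  for (perm in all_perms(ids)) {
    v <- ndcg(perm, ids)
    expect_gt(v, 0)
    expect_lte(v, 1)
    if (v == 1) expect_identical(perm, ids)
  }
})

test_that("a top-3 error is penalised more than a tail error", {
  ids <- sprintf("c%02d", 1:10)
  swap <- function(v, i, j) { v[c(i, j)] <- v[c(j, i)]; v }
  top_err <- 1 - ndcg(swap(ids, 1, 3), ids, p_eval = 3)
  tail_err <- 1 - ndcg(swap(ids, 9, 10), ids, p_eval = 10)
  expect_gt(top_err, tail_err)
})

test_that("evaluate_methods aggregates per split and method", {
  samples <- small_phantoms(30, seed = 19)
  splits <- make_splits(samples, 3, p = 10, seed = 1)
  gt_results <- lapply(splits, function(sp)
    list(split_id = sp$split_id, method_id = "oracle",
         ranking = sp$catalogue_ids))
  ev <- evaluate_methods(splits, gt_results)
  expect_identical(nrow(ev$per_split), 6L)   # 3 splits x 2 truncations
  expect_true(all(ev$per_split$ndcg == 1))
  expect_true(all(ev$summary$median == 1))
  # single split: min = median = max
  ev1 <- evaluate_methods(splits[1], gt_results[1])
  expect_identical(ev1$summary$min, ev1$summary$max)
  # random permutations score strictly below 1 and above the analytic floor
  set.seed(23)
  sp <- splits[[1]]
  floor_ndcg <- min(vapply(all_perms(sp$catalogue_ids[1:5]), function(pm)
    ndcg(c(pm, sp$catalogue_ids[6:10]), sp$catalogue_ids), 1.0))
  rnd <- lapply(1:10, function(i)
    list(split_id = sp$split_id, method_id = paste0("rnd", i),
         ranking = sample(sp$catalogue_ids)))
  evr <- evaluate_methods(splits[1], rnd, p_evals = 10)
  expect_lt(mean(evr$per_split$ndcg), 1)
  expect_gt(mean(evr$per_split$ndcg), floor_ndcg)
  bad <- list(list(split_id = "splitXX", method_id = "m", ranking = letters))
  expect_error(evaluate_methods(splits, bad), "unknown split")
})

test_that("inter-rater comparison scores raters against a reference", {
  samples <- small_phantoms(30, seed = 25)
  splits <- make_splits(samples, 2, p = 10, seed = 3)
  ann <- list()
  for (sp in splits) {
    ann[[length(ann) + 1]] <- list(split_id = sp$split_id, rater_id = "R1",
                                   ranking = sp$catalogue_ids)
    ann[[length(ann) + 1]] <- list(split_id = sp$split_id, rater_id = "R2",
                                   ranking = sp$catalogue_ids)
    ann[[length(ann) + 1]] <- list(split_id = sp$split_id, rater_id = "R3",
                                   ranking = rev(sp$catalogue_ids))
  }
  ir <- interrater(ann, "R1")
  # two scored raters, two splits, two truncations
  expect_identical(nrow(ir$per_split), 8L)
  expect_true(all(ir$per_split$ndcg[ir$per_split$method == "R2"] == 1))
  expect_true(all(ir$per_split$ndcg[ir$per_split$method == "R3"] < 1))
  expect_error(interrater(ann, "R9"), "R9")
  expect_error(interrater(ann[c(1, 4)], "R1"), "at least 2")
  # uniformly random raters are measurably far from the reference
  set.seed(40)
  sp <- splits[[1]]
  rnd_scores <- replicate(50,
    ndcg(sample(sp$catalogue_ids), sp$catalogue_ids))
  expect_lt(mean(rnd_scores), 0.95)
})

test_that("annotation CSV files round-trip", {
  ann <- list(list(split_id = "split01", rater_id = "R2",
                   ranking = sprintf("s%02d", c(3, 1, 2))),
              list(split_id = "split02", rater_id = "R2",
                   ranking = sprintf("s%02d", c(2, 3, 1))))
  path <- withr::local_tempfile(fileext = ".csv")
  write_annotations(ann, path)
  back <- read_annotations(path)
  expect_identical(back, ann)
})
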
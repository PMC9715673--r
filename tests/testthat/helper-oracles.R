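# Independent brute-force oracles and shared fixtures.

# nDCG reimplemented from first principles, kept deliberately naive and
# independent of the package's vectorised implementation.
brute_ndcg <- function(ranking, ground_truth, p_eval = length(ground_truth)) {
  p <- length(ground_truth)
  rel_of <- function(id) {
    i <- match(id, ground_truth)
    1 + 0.5 * (p - i)
  }
  dcg_of <- function(order) {
    s <- 0
    for (i in seq_len(p_eval))
      s <- s + (2^rel_of(order[i]) - 1) / log2(i + 1)
    s
  }
  dcg_of(ranking) / dcg_of(ground_truth)
}

# All permutations of a small vector (n! grows fast; used with n <= 5).
all_perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (rest in all_perms(v[-i]))
      out[[length(out) + 1L]] <- c(v[i], rest)
  out
}

# Random small bias-free ReLU conv/dense network on a [0, 1] image input,
# for relevance-conservation checks.
random_biasfree_net <- function(h = 8L, w = 8L, ch = 1L) {
  ns <- asNamespace("saliret")
  c1 <- ns$layer_conv(3L, 3L, ch, sample(2:5, 1), pad = 1L)
  c1$b[] <- 0
  c2 <- ns$layer_conv(3L, 3L, c1$out_ch, sample(2:4, 1), pad = 1L)
  c2$b[] <- 0
  d <- ns$layer_dense(c2$out_ch, 1L)
  d$b[] <- 0
  m <- list(layers = list(c1, ns$layer_relu(), c2, ns$layer_relu(),
                          ns$layer_gap(), d),
            gap_index = 5L, head = NULL, input_spec = c(h, w, ch),
            feature_dim = c2$out_ch, meta = list())
  class(m) <- "sal_model"
  m
}

# Tiny but complete training dataset (32 x 32 phantoms) for fast training
# mechanics tests.
small_phantoms <- function(n = 24, seed = 42) {
  cfg <- phantom_config(image_size = 32, seed = seed)
  generate_dataset(cfg, n)
}

# Full-scale benchmark fixture, trained once per test run and shared by the
# saliency-localisation and method-separation checks. Study conditions:
# default phantom generator, 600/100/100 partition, tiny backbone at 96x96,
# 10 epochs per model, 10 splits of 10-image catalogues.
benchmark_fixture <- local({
  cache <- new.env(parent = emptyenv())
  function() {
    if (is.null(cache$ev)) {
      dir <- file.path(tempdir(), "saliret-benchmark-fixture")
      cfg <- run_config(seed = 1L)
      cache$ev <- run_benchmark(cfg, dir)
      cache$cfg <- cfg
      cache$dir <- dir
      cache$run <- saliret:::load_run(dir)
    }
    cache
  }
})
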
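# Dual-attention comparator: per-tap self-attention over spatial positions,
# bilinear resizing of coarse taps to the finest tap's grid, a softmax gate
# across levels, and a gated sum feeding global pooling. The fusion is a
# configurable variant of the multi-level dual-attention design, not a
# bit-exact reproduction of any published OCT model.

#' Attention model configuration
#'
#' @param tap_points indices into the backbone's tap list (coarse to fine
#'   semantic depth); `NULL` uses every tap the architecture exposes.
#' @param fusion_dim channels after multi-level fusion; `NULL` defaults to
#'   the channel count of the finest-resolution tap.
#' @param seed integer seed for head weight initialisation.
#' @export
attention_config <- function(tap_points = NULL, fusion_dim = NULL, seed = 1L) {
  structure(list(tap_points = tap_points, fusion_dim = fusion_dim,
                 seed = as.integer(seed)), class = "attention_config")
}

#' Build the attention-driven classifier (ATT)
#'
#' Takes the backbone of `architecture_id`, taps its multi-level feature
#' maps, refines each tap with dot-product self-attention, fuses the levels
#' with a softmax gate, and classifies from the global-average-pooled fused
#' features. The penultimate fused vector implements the embedding used for
#' attention-based retrieval distances.
#'
#' @inheritParams build_backbone
#' @param config an [attention_config()].
#' @return an untrained `sal_model` with an attention head
#'   (`feature_dim = fusion_dim`).
#' @export
build_attention_model <- function(architecture_id = c("tiny", "densenet121"),
                                  input_spec = NULL,
                                  config = attention_config()) {
  model <- build_backbone(architecture_id, input_spec, seed = config$seed)
  shapes <- seq_out_shapes(model$layers, model$input_spec)
  tap_layers <- model$taps
  if (!is.null(config$tap_points)) {
    if (any(config$tap_points < 1L | config$tap_points > length(tap_layers)))
      stop_config("tap_points must index the architecture's %d taps",
                  length(tap_layers))
    tap_layers <- tap_layers[sort(unique(as.integer(config$tap_points)))]
  }
  if (length(tap_layers) < 2L)
    stop_config("attention model needs at least 2 tap points")
  tap_shapes <- shapes[tap_layers]
  # finest grid = largest spatial size among taps
  areas <- vapply(tap_shapes, function(s) s[1] * s[2], 1)
  fin <- which.max(areas)
  fusion_dim <- config$fusion_dim
  if (is.null(fusion_dim)) fusion_dim <- tap_shapes[[fin]][3]
  fusion_dim <- as.integer(fusion_dim)

  head <- with_seed(derive_seed(config$seed, 17L), {
    levels <- lapply(tap_shapes, function(s) {
      C <- s[3]
      d <- max(8L, C %/% 4L)
      list(in_shape = s, d = d,
           Wq = matrix(he_init(C * d, C), C, d),
           Wk = matrix(he_init(C * d, C), C, d),
           Wv = matrix(he_init(C * C, C), C, C) * 0.1,
           Wp = matrix(he_init(C * fusion_dim, C), C, fusion_dim),
           bp = numeric(fusion_dim),
           wg = he_init(fusion_dim, fusion_dim),
           bg = 0)
    })
    list(levels = levels, tap_layers = tap_layers,
         out_hw = tap_shapes[[fin]][1:2], fusion_dim = fusion_dim,
         dense = list(W = matrix(he_init(fusion_dim, fusion_dim),
                                 fusion_dim, 1L), b = 0))
  })
  # drop the backbone's own classifier tail: the head replaces it
  model$layers <- model$layers[seq_len(max(tap_layers))]
  model$gap_index <- NULL
  model$head <- head
  model$feature_dim <- fusion_dim
  model$meta$tap_shapes <- tap_shapes
  model
}

# Self-attention on one tap: X is (P x C); returns refined map + caches.
selfatt_forward <- function(lv, Tl) {
  s <- dim(Tl)
  X <- matrix(Tl, s[1] * s[2], s[3])
  Q <- X %*% lv$Wq
  K <- X %*% lv$Wk
  V <- X %*% lv$Wv
  A <- row_softmax(Q %*% t(K) / sqrt(lv$d))
  O <- X + A %*% V
  list(X = X, Q = Q, K = K, V = V, A = A, O = O, shape = s)
}

att_head_forward <- function(head, taps) {
  L <- length(head$levels)
  oh <- head$out_hw[1]; ow <- head$out_hw[2]
  P1 <- oh * ow
  Fd <- head$fusion_dim
  sa <- vector("list", L)
  U <- vector("list", L)
  S <- matrix(0, P1, L)
  for (l in seq_len(L)) {
    lv <- head$levels[[l]]
    sa[[l]] <- selfatt_forward(lv, taps[[l]])
    Z <- sweep(sa[[l]]$O %*% lv$Wp, 2L, lv$bp, "+")
    s <- sa[[l]]$shape
    if (s[1] != oh || s[2] != ow) {
      Zr <- cpp_resize_bilinear(array(Z, c(s[1], s[2], Fd)),
                                s[1], s[2], Fd, oh, ow)
      U[[l]] <- matrix(Zr, P1, Fd)
    } else U[[l]] <- Z
    S[, l] <- U[[l]] %*% lv$wg + lv$bg
  }
  G <- row_softmax(S)
  fused <- matrix(0, P1, Fd)
  for (l in seq_len(L)) fused <- fused + G[, l] * U[[l]]
  pooled <- colMeans(fused)
  # per-sample embedding standardisation, as in the plain backbone
  mu <- mean(pooled)
  sg <- sqrt(mean((pooled - mu)^2) + 1e-6)
  feature <- (pooled - mu) / sg
  logit <- sum(feature * head$dense$W) + head$dense$b
  list(sa = sa, U = U, G = G, fused = fused, feature = feature, sg = sg,
       logit = logit)
}

att_head_backward <- function(head, hf, g_logit) {
  L <- length(head$levels)
  oh <- head$out_hw[1]; ow <- head$out_hw[2]
  P1 <- oh * ow
  Fd <- head$fusion_dim
  g_norm <- g_logit * drop(head$dense$W)
  g_dense <- list(W = matrix(g_logit * hf$feature, Fd, 1L), b = g_logit)
  g_feature <- (g_norm - mean(g_norm) - hf$feature * mean(g_norm * hf$feature)) / hf$sg
  g_fused <- matrix(rep(g_feature / P1, each = P1), P1, Fd)

  gG <- matrix(0, P1, L)
  gU <- vector("list", L)
  for (l in seq_len(L)) {
    gG[, l] <- rowSums(g_fused * hf$U[[l]])
    gU[[l]] <- hf$G[, l] * g_fused
  }
  # softmax gate backward (row-wise over levels)
  gS <- hf$G * (gG - rowSums(gG * hf$G))
  g_levels <- vector("list", L)
  g_taps <- vector("list", L)
  for (l in seq_len(L)) {
    lv <- head$levels[[l]]
    gU[[l]] <- gU[[l]] + outer(gS[, l], lv$wg)
    gwg <- drop(crossprod(hf$U[[l]], gS[, l]))
    gbg <- sum(gS[, l])
    s <- hf$sa[[l]]$shape
    gZ <- gU[[l]]
    if (s[1] != oh || s[2] != ow) {
      gZr <- cpp_resize_bilinear_bwd(array(gU[[l]], c(oh, ow, Fd)),
                                     s[1], s[2], Fd, oh, ow)
      gZ <- matrix(gZr, s[1] * s[2], Fd)
    }
    gO <- gZ %*% t(lv$Wp)
    gWp <- crossprod(hf$sa[[l]]$O, gZ)
    gbp <- colSums(gZ)
    # self-attention backward
    ca <- hf$sa[[l]]
    gA <- gO %*% t(ca$V)
    gV <- crossprod(ca$A, gO)
    gX <- gO
    gSc <- ca$A * (gA - rowSums(gA * ca$A))
    gQ <- gSc %*% ca$K / sqrt(lv$d)
    gK <- crossprod(gSc, ca$Q) / sqrt(lv$d)
    gX <- gX + gQ %*% t(lv$Wq) + gK %*% t(lv$Wk) + gV %*% t(lv$Wv)
    g_levels[[l]] <- list(Wq = crossprod(ca$X, gQ), Wk = crossprod(ca$X, gK),
                          Wv = crossprod(ca$X, gV), Wp = gWp, bp = gbp,
                          wg = gwg, bg = gbg)
    g_taps[[l]] <- array(gX, s)
  }
  list(grads = list(levels = g_levels, dense = g_dense), g_taps = g_taps)
}

att_head_params <- function(head)
  list(levels = lapply(head$levels, function(lv)
         lv[c("Wq", "Wk", "Wv", "Wp", "bp", "wg", "bg")]),
       dense = head$dense)

att_head_set_params <- function(head, p) {
  for (l in seq_along(head$levels))
    head$levels[[l]][c("Wq", "Wk", "Wv", "Wp", "bp", "wg", "bg")] <-
      p$levels[[l]]
  head$dense <- p$dense
  head
}

#' Attention-model feature vector
#'
#' Deterministic penultimate (fused, global-average-pooled) vector of length
#' `fusion_dim`; the embedding compared by Euclidean distance in
#' attention-based retrieval.
#' @inheritParams extract_features
#' @export
extract_att_features <- function(model, image) {
  if (is.null(model$head)) stop_config("model has no attention head")
  extract_features(model, image)
}
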
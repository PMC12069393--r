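# Token-mixer transformer classifier.
#
# Architecture: learned token + positional embeddings; n pre-norm residual
# blocks, each Y_n = TokenMixer(Norm(Y_{n-1})) + Y_{n-1} followed by
# Y_{n+1} = MLP(Norm(Y_n)) + Y_n, where TokenMixer = STA(MHSA(.)):
# multi-head scaled-dot-product self-attention (Softmax(Q K^T / sqrt(d)) V
# per head, heads concatenated and projected) followed by a short-time
# aggregation layer (dropout -> single-channel 2-D convolution over the
# len x d_model grid with same padding -> reshape -> linear projection).
# The classification head mean-pools non-padding positions and applies a
# linear layer with softmax.  The MLP is two linear layers with ReLU, each
# followed by dropout.
#
# Forward, backward and the AdamW optimizer are implemented directly on R
# matrices (BLAS does the heavy lifting); gradients are verified against
# finite differences in the test suite.

#' Model configuration
#'
#' @param n_layers Number of transformer blocks (default 2).
#' @param d_model Embedding width (default 128; divisible by `n_heads`).
#' @param n_heads Attention heads (default 4).
#' @param mlp_hidden MLP hidden width (default 256).
#' @param dropout Dropout probability (default 0.1).
#' @param conv_kernel STA convolution kernel size (default 3, i.e. 3x3).
#' @param max_len Token sequence length (default 128).
#' @param n_classes Number of classes K (default 4).
#' @param seed Weight-initialization seed.
#' @return Object of class `model_config`.
#' @export
model_config <- function(n_layers = 2, d_model = 128, n_heads = 4,
                         mlp_hidden = 256, dropout = 0.1, conv_kernel = 3,
                         max_len = 128, n_classes = 4, seed = 1) {
  stopifnot(n_layers >= 1, d_model >= 1, n_heads >= 1,
            d_model %% n_heads == 0, mlp_hidden >= 1,
            dropout >= 0, dropout < 1, conv_kernel >= 1,
            max_len >= 1, n_classes >= 2)
  structure(as.list(environment()), class = "model_config")
}

#' Training configuration
#'
#' Defaults follow the study settings: AdamW, learning rate 5e-5,
#' 5 epochs, batch size 2, sequence length 128, training loss as the
#' monitored metric.
#'
#' @param learning_rate AdamW learning rate (default 5e-5).
#' @param epochs Training epochs (default 5).
#' @param batch_size Mini-batch size (default 2).
#' @param weight_decay Decoupled weight decay on weight matrices (0.01).
#' @param seed Seed for shuffling, dropout and splitting.
#' @return Object of class `train_config`.
#' @export
train_config <- function(learning_rate = 5e-5, epochs = 5, batch_size = 2,
                         weight_decay = 0.01, seed = 1) {
  stopifnot(learning_rate > 0, epochs >= 1, batch_size >= 1,
            weight_decay >= 0)
  structure(as.list(environment()), class = "train_config")
}

rmat <- function(nr, nc, sd) matrix(stats::rnorm(nr * nc, 0, sd), nr, nc)

#' Initialize a token-mixer model
#'
#' @param mconf A [model_config()].
#' @param vocab_size Vocabulary size for the embedding table.
#' @return Object of class `token_mixer_model` (weights + config).
#' @export
init_token_mixer <- function(mconf, vocab_size) {
  stopifnot(inherits(mconf, "model_config"), vocab_size >= 1)
  set.seed(mconf$seed)
  d <- mconf$d_model
  xav <- function(nr, nc) rmat(nr, nc, sqrt(2 / (nr + nc)))
  layer <- function() list(
    ln1_g = rep(1, d), ln1_b = rep(0, d),
    Wq = xav(d, d), bq = rep(0, d),
    Wk = xav(d, d), bk = rep(0, d),
    Wv = xav(d, d), bv = rep(0, d),
    Wo = xav(d, d), bo = rep(0, d),
    conv_k = rmat(mconf$conv_kernel, mconf$conv_kernel, 0.1),
    conv_b = 0,
    Wsta = xav(d, d), bsta = rep(0, d),
    ln2_g = rep(1, d), ln2_b = rep(0, d),
    W1 = xav(d, mconf$mlp_hidden), b1 = rep(0, mconf$mlp_hidden),
    W2 = xav(mconf$mlp_hidden, d), b2 = rep(0, d)
  )
  params <- list(
    emb = rmat(vocab_size, d, 0.1),
    pos = rmat(mconf$max_len, d, 0.1),
    layers = lapply(seq_len(mconf$n_layers), function(i) layer()),
    Wc = xav(d, mconf$n_classes), bc = rep(0, mconf$n_classes)
  )
  structure(list(params = params, config = mconf, vocab_size = vocab_size),
            class = "token_mixer_model")
}

## ---- primitive layers -----------------------------------------------------

layernorm_fwd <- function(x, g, b, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc^2)
  istd <- 1 / sqrt(v + eps)
  xhat <- xc * istd
  n <- nrow(x)
  list(y = xhat * rep(g, each = n) + rep(b, each = n),
       xhat = xhat, istd = istd)
}

layernorm_bwd <- function(dy, cache, g) {
  xhat <- cache$xhat
  dxhat <- dy * rep(g, each = nrow(dy))
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  dx <- (dxhat - m1 - xhat * m2) * cache$istd
  list(dx = dx, dg = colSums(dy * xhat), db = colSums(dy))
}

softmax_rows <- function(s) {
  mx <- s[cbind(seq_len(nrow(s)), max.col(s, ties.method = "first"))]
  e <- exp(s - mx)
  e / rowSums(e)
}

dropout_fwd <- function(x, p, training) {
  if (!training || p <= 0) return(list(y = x, mask = NULL))
  mask <- matrix(stats::runif(length(x)) >= p, nrow(x), ncol(x)) / (1 - p)
  list(y = x * mask, mask = mask)
}

dropout_bwd <- function(dy, mask) if (is.null(mask)) dy else dy * mask

# single-channel 2-D convolution with same (zero) padding
shift_mat <- function(x, di, dj) {
  nr <- nrow(x); nc <- ncol(x)
  y <- matrix(0, nr, nc)
  ri <- max(1, 1 - di):min(nr, nr - di)
  ci <- max(1, 1 - dj):min(nc, nc - dj)
  y[ri, ci] <- x[ri + di, ci + dj]
  y
}

pad_mat <- function(x, r) {
  p <- matrix(0, nrow(x) + 2 * r, ncol(x) + 2 * r)
  p[(r + 1):(r + nrow(x)), (r + 1):(r + ncol(x))] <- x
  p
}

conv2d_fwd <- function(x, k, bias) {
  ks <- nrow(k)
  if (ks > nrow(x) || ks > ncol(x)) {
    stop("convolution kernel larger than the token grid")
  }
  r <- (ks - 1) %/% 2
  p <- pad_mat(x, r)
  ri <- seq_len(nrow(x)); ci <- seq_len(ncol(x))
  y <- matrix(bias, nrow(x), ncol(x))
  for (a in seq_len(ks)) for (b in seq_len(ks)) {
    y <- y + k[a, b] * p[ri + (a - 1), ci + (b - 1), drop = FALSE]
  }
  y
}

conv2d_bwd <- function(dy, x, k) {
  ks <- nrow(k)
  r <- (ks - 1) %/% 2
  px <- pad_mat(x, r)
  pdy <- pad_mat(dy, r)
  ri <- seq_len(nrow(x)); ci <- seq_len(ncol(x))
  dk <- matrix(0, ks, ks)
  dx <- matrix(0, nrow(x), ncol(x))
  for (a in seq_len(ks)) for (b in seq_len(ks)) {
    dk[a, b] <- sum(dy * px[ri + (a - 1), ci + (b - 1), drop = FALSE])
    dx <- dx + k[a, b] * pdy[ri + (2 * r - (a - 1)), ci + (2 * r - (b - 1)),
                             drop = FALSE]
  }
  list(dk = dk, dx = dx, dbias = sum(dy))
}

## ---- spec-surface operations ---------------------------------------------

#' Multi-head self-attention
#'
#' Per head: Q, K, V linear projections of the input, scaled dot-product
#' attention `Softmax(Q K^T / sqrt(d)) V` with `d` the per-head width;
#' heads are concatenated and projected back to `d_model`.  Contains no
#' positional information, so it is permutation-equivariant.
#'
#' @param tokens `len x d_model` matrix.
#' @param state Layer weights (`Wq,bq,Wk,bk,Wv,bv,Wo,bo`).
#' @param n_heads Number of heads.
#' @param key_mask Optional 0/1 vector: positions with 0 are masked out of
#'   the attention keys.
#' @param want_cache Internal: return backward cache.
#' @return `len x d_model` matrix (attribute `attn`: list of per-head
#'   attention matrices).
#' @export
mhsa <- function(tokens, state, n_heads, key_mask = NULL, want_cache = FALSE) {
  if (!all(is.finite(tokens))) stop("non-finite attention input")
  d <- ncol(tokens)
  dh <- d %/% n_heads
  Q <- tokens %*% state$Wq + rep(state$bq, each = nrow(tokens))
  K <- tokens %*% state$Wk + rep(state$bk, each = nrow(tokens))
  V <- tokens %*% state$Wv + rep(state$bv, each = nrow(tokens))
  H <- matrix(0, nrow(tokens), d)
  attn <- vector("list", n_heads)
  for (h in seq_len(n_heads)) {
    cols <- ((h - 1) * dh + 1):(h * dh)
    S <- tcrossprod(Q[, cols, drop = FALSE], K[, cols, drop = FALSE]) / sqrt(dh)
    if (!is.null(key_mask)) S[, key_mask == 0] <- -1e9
    P <- softmax_rows(S)
    attn[[h]] <- P
    H[, cols] <- P %*% V[, cols, drop = FALSE]
  }
  out <- H %*% state$Wo + rep(state$bo, each = nrow(tokens))
  attr(out, "attn") <- attn
  if (want_cache) {
    attr(out, "cache") <- list(Q = Q, K = K, V = V, H = H, attn = attn)
  }
  out
}

mhsa_bwd <- function(dout, tokens, state, n_heads, cache) {
  d <- ncol(tokens); dh <- d %/% n_heads
  n <- nrow(tokens)
  dH <- tcrossprod(dout, state$Wo)
  g <- list(Wo = crossprod(cache$H, dout), bo = colSums(dout))
  dQ <- matrix(0, n, d); dK <- matrix(0, n, d); dV <- matrix(0, n, d)
  for (h in seq_len(n_heads)) {
    cols <- ((h - 1) * dh + 1):(h * dh)
    P <- cache$attn[[h]]
    dHh <- dH[, cols, drop = FALSE]
    Vh <- cache$V[, cols, drop = FALSE]
    dV[, cols] <- crossprod(P, dHh)
    dP <- tcrossprod(dHh, Vh)
    dS <- P * (dP - rowSums(dP * P))
    dQ[, cols] <- (dS %*% cache$K[, cols, drop = FALSE]) / sqrt(dh)
    dK[, cols] <- crossprod(dS, cache$Q[, cols, drop = FALSE]) / sqrt(dh)
  }
  g$Wq <- crossprod(tokens, dQ); g$bq <- colSums(dQ)
  g$Wk <- crossprod(tokens, dK); g$bk <- colSums(dK)
  g$Wv <- crossprod(tokens, dV); g$bv <- colSums(dV)
  dx <- tcrossprod(dQ, state$Wq) + tcrossprod(dK, state$Wk) +
    tcrossprod(dV, state$Wv)
  list(dx = dx, grads = g)
}

#' Short-time aggregation layer
#'
#' Dropout on the attention output, a single-channel 2-D convolution over
#' the `len x d_model` grid with same padding, reshape back, and a linear
#' projection.  Deterministic with dropout off (evaluation mode).
#'
#' @param att_output `len x d_model` matrix.
#' @param state Layer weights (`conv_k`, `conv_b`, `Wsta`, `bsta`).
#' @param dropout Dropout probability.
#' @param training Apply dropout?
#' @return `len x d_model` matrix.
#' @export
sta <- function(att_output, state, dropout = 0, training = FALSE) {
  dr <- dropout_fwd(att_output, dropout, training)
  conv <- conv2d_fwd(dr$y, state$conv_k, state$conv_b)
  conv %*% state$Wsta + rep(state$bsta, each = nrow(att_output))
}

#' One pre-norm transformer block (evaluation mode)
#'
#' `Y_n = STA(MHSA(Norm(Y_{n-1}))) + Y_{n-1}` followed by
#' `Y_{n+1} = MLP(Norm(Y_n)) + Y_n`.
#'
#' @param y_prev `len x d_model` matrix.
#' @param state Full layer weight list (see [init_token_mixer()]).
#' @param n_heads Attention heads.
#' @param key_mask Optional 0/1 attention key mask.
#' @return `len x d_model` matrix.
#' @export
transformer_block <- function(y_prev, state, n_heads, key_mask = NULL) {
  a <- layernorm_fwd(y_prev, state$ln1_g, state$ln1_b)$y
  m <- mhsa(a, state, n_heads, key_mask)
  y1 <- y_prev + sta(m, state)
  b <- layernorm_fwd(y1, state$ln2_g, state$ln2_b)$y
  u <- pmax(b %*% state$W1 + rep(state$b1, each = nrow(b)), 0)
  y1 + u %*% state$W2 + rep(state$b2, each = nrow(b))
}

## ---- full forward / backward ---------------------------------------------

forward_sample <- function(model, ids, mask, training = FALSE) {
  p <- model$params
  mc <- model$config
  if (length(ids) != mc$max_len) {
    stop("sequence length ", length(ids), " does not match config max_len ",
         mc$max_len)
  }
  drp <- if (training) mc$dropout else 0
  x <- p$emb[ids + 1L, , drop = FALSE] + p$pos
  caches <- vector("list", mc$n_layers)
  for (li in seq_len(mc$n_layers)) {
    st <- p$layers[[li]]
    ln1 <- layernorm_fwd(x, st$ln1_g, st$ln1_b)
    m <- mhsa(ln1$y, st, mc$n_heads, key_mask = mask, want_cache = TRUE)
    dr1 <- dropout_fwd(m, drp, training)
    conv <- conv2d_fwd(dr1$y, st$conv_k, st$conv_b)
    s_out <- conv %*% st$Wsta + rep(st$bsta, each = mc$max_len)
    x1 <- x + s_out
    ln2 <- layernorm_fwd(x1, st$ln2_g, st$ln2_b)
    upre <- ln2$y %*% st$W1 + rep(st$b1, each = mc$max_len)
    u <- pmax(upre, 0)
    dr2 <- dropout_fwd(u, drp, training)
    o <- dr2$y %*% st$W2 + rep(st$b2, each = mc$max_len)
    dr3 <- dropout_fwd(o, drp, training)
    x2 <- x1 + dr3$y
    caches[[li]] <- list(x_in = x, ln1 = ln1, mcache = attr(m, "cache"),
                         mval = strip_attrs(m), dr1 = dr1, conv_in = dr1$y,
                         conv = conv, x1 = x1, ln2 = ln2, upre = upre,
                         dr2 = dr2, x2 = x2, dr3 = dr3)
    x <- x2
  }
  w <- mask / sum(mask)
  pool <- as.numeric(crossprod(x, w))
  logits <- as.numeric(pool %*% p$Wc) + p$bc
  probs <- { e <- exp(logits - max(logits)); e / sum(e) }
  list(probs = probs, logits = logits, pool = pool, x_final = x,
       caches = caches, ids = ids, mask = mask, w = w)
}

strip_attrs <- function(m) { attributes(m) <- list(dim = dim(m)); m }

backward_sample <- function(model, fw, dlogits) {
  p <- model$params
  mc <- model$config
  g <- list(Wc = outer(fw$pool, dlogits), bc = dlogits,
            layers = vector("list", mc$n_layers))
  dpool <- as.numeric(p$Wc %*% dlogits)
  dx <- outer(fw$w, dpool)
  for (li in rev(seq_len(mc$n_layers))) {
    st <- p$layers[[li]]
    ca <- fw$caches[[li]]
    gl <- list()
    # MLP sublayer
    do_ <- dropout_bwd(dx, ca$dr3$mask)
    gl$W2 <- crossprod(ca$dr2$y, do_); gl$b2 <- colSums(do_)
    du <- dropout_bwd(tcrossprod(do_, st$W2), ca$dr2$mask)
    du <- du * (ca$upre > 0)
    gl$W1 <- crossprod(ca$ln2$y, du); gl$b1 <- colSums(du)
    dln2 <- layernorm_bwd(tcrossprod(du, st$W1), ca$ln2, st$ln2_g)
    gl$ln2_g <- dln2$dg; gl$ln2_b <- dln2$db
    dx1 <- dx + dln2$dx
    # STA sublayer
    dsta <- dx1
    gl$Wsta <- crossprod(ca$conv, dsta); gl$bsta <- colSums(dsta)
    dconv <- tcrossprod(dsta, st$Wsta)
    cb <- conv2d_bwd(dconv, ca$conv_in, st$conv_k)
    gl$conv_k <- cb$dk; gl$conv_b <- cb$dbias
    dm <- dropout_bwd(cb$dx, ca$dr1$mask)
    mb <- mhsa_bwd(dm, ca$ln1$y, st, mc$n_heads, ca$mcache)
    gl[names(mb$grads)] <- mb$grads
    dln1 <- layernorm_bwd(mb$dx, ca$ln1, st$ln1_g)
    gl$ln1_g <- dln1$dg; gl$ln1_b <- dln1$db
    dx <- dx1 + dln1$dx
    g$layers[[li]] <- gl
  }
  g$pos <- dx
  g$emb <- list(ids = fw$ids, d = dx)  # sparse embedding gradient
  g
}

## ---- optimizer ------------------------------------------------------------

adamw_state <- function(params) {
  zero_like <- function(x) {
    if (is.list(x)) lapply(x, zero_like) else x * 0
  }
  list(m = zero_like(params), v = zero_like(params), t = 0L)
}

# Flat walker over the parameter tree; embedding gets a sparse update.
adamw_update <- function(model, grads, opt, tconf) {
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  opt$t <- opt$t + 1L
  bc1 <- 1 - b1^opt$t; bc2 <- 1 - b2^opt$t
  lr <- tconf$learning_rate; wd <- tconf$weight_decay
  upd <- function(p, g, m, v, decay) {
    m <- b1 * m + (1 - b1) * g
    v <- b2 * v + (1 - b2) * g^2
    step <- lr * ((m / bc1) / (sqrt(v / bc2) + eps) + decay * p)
    list(p = p - step, m = m, v = v)
  }
  decay_of <- function(name) {
    if (grepl("^(W|conv_k|emb|pos)", name)) tconf$weight_decay else 0
  }
  # embedding: densify the sparse gradient (rows repeat for repeated ids)
  ge <- matrix(0, nrow(model$params$emb), ncol(model$params$emb))
  rows <- grads$emb$ids + 1L
  for (i in seq_along(rows)) {
    ge[rows[i], ] <- ge[rows[i], ] + grads$emb$d[i, ]
  }
  r <- upd(model$params$emb, ge, opt$m$emb, opt$v$emb, wd)
  model$params$emb <- r$p; opt$m$emb <- r$m; opt$v$emb <- r$v
  r <- upd(model$params$pos, grads$pos, opt$m$pos, opt$v$pos, wd)
  model$params$pos <- r$p; opt$m$pos <- r$m; opt$v$pos <- r$v
  for (nm in c("Wc", "bc")) {
    r <- upd(model$params[[nm]], grads[[nm]], opt$m[[nm]], opt$v[[nm]],
             decay_of(nm))
    model$params[[nm]] <- r$p; opt$m[[nm]] <- r$m; opt$v[[nm]] <- r$v
  }
  for (li in seq_along(model$params$layers)) {
    for (nm in names(model$params$layers[[li]])) {
      r <- upd(model$params$layers[[li]][[nm]], grads$layers[[li]][[nm]],
               opt$m$layers[[li]][[nm]], opt$v$layers[[li]][[nm]],
               decay_of(nm))
      model$params$layers[[li]][[nm]] <- r$p
      opt$m$layers[[li]][[nm]] <- r$m
      opt$v$layers[[li]][[nm]] <- r$v
    }
  }
  list(model = model, opt = opt)
}

add_grads <- function(a, b) {
  if (is.null(a)) return(b)
  a$Wc <- a$Wc + b$Wc; a$bc <- a$bc + b$bc; a$pos <- a$pos + b$pos
  a$emb$ids <- c(a$emb$ids, b$emb$ids)
  a$emb$d <- rbind(a$emb$d, b$emb$d)
  for (li in seq_along(a$layers)) {
    for (nm in names(a$layers[[li]])) {
      a$layers[[li]][[nm]] <- a$layers[[li]][[nm]] + b$layers[[li]][[nm]]
    }
  }
  a
}

scale_grads <- function(g, s) {
  g$Wc <- g$Wc * s; g$bc <- g$bc * s; g$pos <- g$pos * s
  g$emb$d <- g$emb$d * s
  for (li in seq_along(g$layers)) {
    for (nm in names(g$layers[[li]])) {
      g$layers[[li]][[nm]] <- g$layers[[li]][[nm]] * s
    }
  }
  g
}

## ---- classify / train -----------------------------------------------------

#' Class probabilities for one tokenized sample
#'
#' @param sample A `tokenized_sample`.
#' @param model A trained (or initialized) `token_mixer_model`.
#' @return Numeric probability vector of length K (sums to 1); the
#'   predicted class is the argmax, ties resolved to the lowest label id.
#' @export
classify <- function(sample, model) {
  stopifnot(inherits(model, "token_mixer_model"))
  fw <- forward_sample(model, sample$token_ids, sample$attention_mask,
                       training = FALSE)
  fw$probs
}

#' Predicted label ids for a list of samples
#' @param samples List of `tokenized_sample`s.
#' @param model A `token_mixer_model`.
#' @return List with `pred` (0-based ids) and `probs` (n x K matrix).
#' @export
classify_batch <- function(samples, model) {
  probs <- t(vapply(samples, classify, numeric(model$config$n_classes),
                    model = model))
  list(pred = max.col(probs, ties.method = "first") - 1L, probs = probs)
}

#' Train the token-mixer classifier
#'
#' Cross-entropy objective, AdamW, settings from [train_config()].  The
#' corpus is split 70-10-20 (stratified, seeded) unless explicit index
#' sets are supplied; the checkpoint with the best validation accuracy is
#' returned.
#'
#' @param corpus List of `tokenized_sample`s with `label_id` set.
#' @param mconf A [model_config()].
#' @param tconf A [train_config()].
#' @param vocab_size Vocabulary size (embedding rows).
#' @param split Fractions (train, val, test) if `split_idx` is NULL.
#' @param split_idx Optional list(train=, val=, test=) of row indices.
#' @return List: `model` (best-validation checkpoint), `final_model`,
#'   `history` (per-epoch training loss and validation accuracy),
#'   `split_idx`.
#' @export
train_token_mixer <- function(corpus, mconf, tconf, vocab_size,
                              split = c(0.7, 0.1, 0.2), split_idx = NULL) {
  labs <- vapply(corpus, function(s) s$label_id, integer(1))
  if (length(unique(labs)) < 2) stop("corpus contains a single class")
  if (is.null(split_idx)) {
    split_idx <- stratified_split(labs, split, seed = tconf$seed)
  }
  set.seed(derive_seed(tconf$seed, "train"))
  model <- init_token_mixer(mconf, vocab_size)
  opt <- adamw_state(model$params)
  tr <- split_idx$train
  va <- split_idx$val
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_accuracy = numeric(0))
  best <- list(acc = -Inf, model = model)
  for (ep in seq_len(tconf$epochs)) {
    ord <- sample(tr)
    losses <- numeric(0)
    i <- 1
    while (i <= length(ord)) {
      bidx <- ord[i:min(i + tconf$batch_size - 1, length(ord))]
      g <- NULL
      bl <- 0
      for (ix in bidx) {
        s <- corpus[[ix]]
        fw <- forward_sample(model, s$token_ids, s$attention_mask,
                             training = TRUE)
        y <- s$label_id + 1L
        bl <- bl - log(max(fw$probs[y], 1e-12))
        dlogits <- fw$probs
        dlogits[y] <- dlogits[y] - 1
        g <- add_grads(g, backward_sample(model, fw, dlogits))
      }
      g <- scale_grads(g, 1 / length(bidx))
      losses <- c(losses, bl / length(bidx))
      res <- adamw_update(model, g, opt, tconf)
      model <- res$model; opt <- res$opt
      i <- i + tconf$batch_size
    }
    val_acc <- if (length(va)) {
      cb <- classify_batch(corpus[va], model)
      mean(cb$pred == labs[va])
    } else NA_real_
    history <- rbind(history, data.frame(
      epoch = ep, train_loss = mean(losses), val_accuracy = val_acc))
    cvd_log("epoch %d: train loss %.4f, val accuracy %s", ep, mean(losses),
            ifelse(is.na(val_acc), "NA", sprintf("%.4f", val_acc)))
    if (!is.na(val_acc) && val_acc > best$acc) {
      best <- list(acc = val_acc, model = model)
    }
  }
  if (!is.finite(best$acc)) best$model <- model
  list(model = best$model, final_model = model, history = history,
       split_idx = split_idx)
}
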
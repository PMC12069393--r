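test_that("MHSA matches a brute-force attention oracle on a 3-token toy", {
  set.seed(30)
  len <- 3; d <- 4; n_heads <- 2; dh <- d / n_heads
  x <- matrix(rnorm(len * d), len, d)
  st <- list(Wq = matrix(rnorm(d * d, 0, 0.5), d, d), bq = rnorm(d),
             Wk = matrix(rnorm(d * d, 0, 0.5), d, d), bk = rnorm(d),
             Wv = matrix(rnorm(d * d, 0, 0.5), d, d), bv = rnorm(d),
             Wo = diag(d), bo = rep(0, d))
  out <- mhsa(x, st, n_heads)
  for (h in 1:n_heads) {
    cols <- ((h - 1) * dh + 1):(h * dh)
    ref <- oracle_attention(x, st$Wq[, cols], st$bq[cols],
                            st$Wk[, cols], st$bk[cols],
                            st$Wv[, cols], st$bv[cols])
    expect_equal(unname(out[, cols]), unname(ref), tolerance = 1e-6)
  }
})

test_that("attention rows sum to one", {
  set.seed(31)
  x <- matrix(rnorm(6 * 8), 6, 8)
  st <- list(Wq = diag(8), bq = rep(0, 8), Wk = diag(8), bk = rep(0, 8),
             Wv = diag(8), bv = rep(0, 8), Wo = diag(8), bo = rep(0, 8))
  out <- mhsa(x, st, 2)
  for (P in attr(out, "attn")) {
    expect_equal(rowSums(P), rep(1, 6), tolerance = 1e-6)
  }
})

test_that("single-token attention is the projection of its own value", {
  set.seed(32)
  d <- 6
  x <- matrix(rnorm(d), 1, d)
  st <- list(Wq = matrix(rnorm(d * d), d, d), bq = rnorm(d),
             Wk = matrix(rnorm(d * d), d, d), bk = rnorm(d),
             Wv = matrix(rnorm(d * d), d, d), bv = rnorm(d),
             Wo = matrix(rnorm(d * d), d, d), bo = rnorm(d))
  out <- mhsa(x, st, 2)
  v <- x %*% st$Wv + st$bv
  expect_equal(out, v %*% st$Wo + st$bo, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(as.numeric(attr(out, "attn")[[1]]), 1)
})

test_that("MHSA is permutation-equivariant; the full token mixer is not", {
  set.seed(33)
  len <- 5; d <- 8
  x <- matrix(rnorm(len * d), len, d)
  mc <- model_config(n_layers = 1, d_model = d, n_heads = 2, mlp_hidden = 8,
                     dropout = 0, max_len = len, seed = 2)
  st <- init_token_mixer(mc, 10)$params$layers[[1]]
  perm <- c(3, 1, 5, 2, 4)
  m1 <- mhsa(x, st, 2)
  m2 <- mhsa(x[perm, ], st, 2)
  expect_equal(m2, m1[perm, ], tolerance = 1e-9, ignore_attr = TRUE)
  tm <- function(z) sta(mhsa(z, st, 2), st)
  t1 <- tm(x); t2 <- tm(x[perm, ])
  expect_gt(max(abs(t2 - t1[perm, ])), 1e-4)
})

test_that("STA preserves shape, is deterministic in eval mode, and scales", {
  set.seed(34)
  x <- matrix(rnorm(2 * 2), 2, 2)
  st <- list(conv_k = matrix(2.5, 1, 1), conv_b = 0, Wsta = diag(2),
             bsta = rep(0, 2))
  expect_equal(sta(x, st), 2.5 * x, tolerance = 1e-12)
  x2 <- matrix(rnorm(7 * 8), 7, 8)
  st2 <- list(conv_k = matrix(rnorm(9), 3, 3), conv_b = 0.3,
              Wsta = matrix(rnorm(64), 8, 8), bsta = rnorm(8))
  o1 <- sta(x2, st2); o2 <- sta(x2, st2)
  expect_equal(dim(o1), dim(x2))
  expect_identical(o1, o2)
  expect_error(sta(matrix(1, 2, 2), st2), "kernel larger")
})

test_that("transformer block is the identity under zeroed sublayer weights", {
  mc <- model_config(n_layers = 1, d_model = 8, n_heads = 2, mlp_hidden = 12,
                     dropout = 0, max_len = 4, seed = 3)
  st <- init_token_mixer(mc, 10)$params$layers[[1]]
  for (nm in c("Wq", "bq", "Wk", "bk", "Wv", "bv", "Wo", "bo", "conv_k",
               "Wsta", "bsta", "W1", "b1", "W2", "b2")) {
    st[[nm]][] <- 0
  }
  st$conv_b <- 0
  set.seed(3)
  x <- matrix(rnorm(4 * 8), 4, 8)
  expect_equal(transformer_block(x, st, 2), x, tolerance = 1e-14)
})

test_that("block outputs stay finite over many random inputs", {
  mc <- model_config(n_layers = 1, d_model = 16, n_heads = 4, mlp_hidden = 24,
                     dropout = 0, max_len = 8, seed = 4)
  st <- init_token_mixer(mc, 10)$params$layers[[1]]
  for (s in 1:100) {
    set.seed(s)
    x <- matrix(rnorm(8 * 16), 8, 16)
    y <- transformer_block(x, st, 4)
    expect_true(all(is.finite(y)))
  }
})

test_that("analytic gradients match finite differences everywhere", {
  mc <- model_config(n_layers = 2, d_model = 8, n_heads = 2, mlp_hidden = 12,
                     dropout = 0, conv_kernel = 3, max_len = 6, n_classes = 3,
                     seed = 7)
  m <- init_token_mixer(mc, vocab_size = 11)
  ids <- c(2L, 5L, 7L, 1L, 0L, 0L)
  mask <- c(1L, 1L, 1L, 1L, 0L, 0L)
  lab <- 2L
  lossfn <- function(model) {
    -log(cvdmix:::forward_sample(model, ids, mask, FALSE)$probs[lab + 1])
  }
  fw <- cvdmix:::forward_sample(m, ids, mask, FALSE)
  dl <- fw$probs; dl[lab + 1] <- dl[lab + 1] - 1
  g <- cvdmix:::backward_sample(m, fw, dl)
  eps <- 1e-6
  set.seed(99)
  for (nm in c("Wq", "Wk", "Wv", "Wo", "conv_k", "conv_b", "Wsta", "W1",
               "W2", "ln1_g", "ln1_b", "ln2_g", "ln2_b", "bq", "bo",
               "bsta", "b1", "b2")) {
    for (li in 1:2) {
      p0 <- m$params$layers[[li]][[nm]]
      i <- sample(length(p0), 1)
      mp <- m; mp$params$layers[[li]][[nm]][i] <- p0[i] + eps
      mm <- m; mm$params$layers[[li]][[nm]][i] <- p0[i] - eps
      num <- (lossfn(mp) - lossfn(mm)) / (2 * eps)
      expect_equal(g$layers[[li]][[nm]][i], num, tolerance = 1e-4,
                   label = sprintf("grad %s layer %d", nm, li))
    }
  }
  # head, positional and (densified) embedding gradients
  for (nm in c("Wc", "bc", "pos")) {
    p0 <- m$params[[nm]]
    i <- sample(length(p0), 1)
    mp <- m; mp$params[[nm]][i] <- p0[i] + eps
    mm <- m; mm$params[[nm]][i] <- p0[i] - eps
    num <- (lossfn(mp) - lossfn(mm)) / (2 * eps)
    expect_equal(g[[nm]][i], num, tolerance = 1e-4, label = nm)
  }
  ge <- matrix(0, 11, 8)
  for (i in seq_along(g$emb$ids)) {
    ge[g$emb$ids[i] + 1, ] <- ge[g$emb$ids[i] + 1, ] + g$emb$d[i, ]
  }
  i <- which(ge != 0)[5]
  mp <- m; mp$params$emb[i] <- mp$params$emb[i] + eps
  mm <- m; mm$params$emb[i] <- mm$params$emb[i] - eps
  num <- (lossfn(mp) - lossfn(mm)) / (2 * eps)
  expect_equal(ge[i], num, tolerance = 1e-4, label = "emb")
})

test_that("classification returns normalized probabilities, deterministically", {
  tk <- make_tiny_corpus(n_per_class = 2)
  m <- init_token_mixer(tiny_model_config(), tk$vocab$size)
  p1 <- classify(tk$samples[[1]], m)
  p2 <- classify(tk$samples[[1]], m)
  expect_equal(sum(p1), 1, tolerance = 1e-6)
  expect_true(all(p1 >= 0))
  expect_identical(p1, p2)
  bad <- tk$samples[[1]]
  bad$token_ids <- bad$token_ids[1:10]
  bad$attention_mask <- bad$attention_mask[1:10]
  expect_error(classify(bad, m), "max_len")
})

test_that("training reduces the loss and is seed-reproducible", {
  tk <- make_tiny_corpus(n_per_class = 12, separation = 6, seed = 3)
  mc <- tiny_model_config()
  tc <- train_config(learning_rate = 5e-4, epochs = 3, batch_size = 4,
                     seed = 11)
  f1 <- suppressMessages(train_token_mixer(tk$samples, mc, tc,
                                           tk$vocab$size))
  expect_lt(f1$history$train_loss[3], f1$history$train_loss[1])
  f2 <- suppressMessages(train_token_mixer(tk$samples, mc, tc,
                                           tk$vocab$size))
  expect_identical(f1$final_model$params, f2$final_model$params)
  expect_identical(f1$history, f2$history)
  # split sizes follow the 70-10-20 fractions
  # split respects the fractions to within one sample per class
  sizes <- vapply(f1$split_idx, length, integer(1))
  expect_equal(sum(sizes), 48L)
  expect_true(all(abs(sizes - 48 * c(0.7, 0.1, 0.2)) <= 4))
})
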
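# Shared fixtures and independent oracles (built in code; no stored data).

# Brute-force scaled-dot-product attention, written independently of the
# package implementation (explicit loops, no masking, single head slice).
oracle_attention <- function(x, Wq, bq, Wk, bk, Wv, bv) {
  n <- nrow(x); dh <- ncol(Wq)
  Q <- matrix(NA_real_, n, dh); K <- Q; V <- Q
  for (i in 1:n) {
    for (j in 1:dh) {
      Q[i, j] <- sum(x[i, ] * Wq[, j]) + bq[j]
      K[i, j] <- sum(x[i, ] * Wk[, j]) + bk[j]
      V[i, j] <- sum(x[i, ] * Wv[, j]) + bv[j]
    }
  }
  out <- matrix(NA_real_, n, dh)
  for (i in 1:n) {
    s <- numeric(n)
    for (t in 1:n) s[t] <- sum(Q[i, ] * K[t, ]) / sqrt(dh)
    w <- exp(s) / sum(exp(s))
    for (j in 1:dh) out[i, j] <- sum(w * V[, j])
  }
  out
}

# Canonical test confusion matrix: 240 test samples, 60 per class, exactly
# one true-CHF sample predicted AFF, everything else correct.
canonical_confusion <- function() {
  cm <- diag(c(60L, 60L, 60L, 60L))
  dimnames(cm) <- list(CVD_CLASSES, CVD_CLASSES)
  cm["CHF", "CHF"] <- 59L
  cm["CHF", "AFF"] <- 1L
  cm
}

# Mann-Whitney AUC oracle by explicit pair counting.
oracle_auc_pairs <- function(scores, positive) {
  pos <- scores[positive]; neg <- scores[!positive]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + (p > q) + 0.5 * (p == q)
  }
  tot / (length(pos) * length(neg))
}

# A tiny tokenized corpus derived from a separable synthetic feature table.
make_tiny_corpus <- function(n_per_class = 15, separation = 6, seed = 3,
                             n_feats = 6, max_len = 48) {
  tab <- generate_feature_table(n_per_class, separation = separation,
                                seed = seed)
  sel <- attr(tab, "informative")[seq_len(n_feats)]
  texts <- vapply(seq_len(nrow(tab)), function(i) {
    serialize_features(unlist(tab[i, feature_registry()$name]), sel)
  }, character(1))
  tokenize_corpus(texts, tab$label, max_len = max_len)
}

tiny_model_config <- function(max_len = 48, seed = 1) {
  model_config(n_layers = 1, d_model = 32, n_heads = 2, mlp_hidden = 48,
               dropout = 0.1, max_len = max_len, n_classes = 4, seed = seed)
}
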
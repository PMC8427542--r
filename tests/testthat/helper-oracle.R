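# Independent nested-loop oracles. These deliberately re-derive every layer
# from its defining formula with plain loops, sharing no code with the
# package's vectorized or compiled paths.

oracle_conv <- function(X, W, b) {
  L <- nrow(X); M <- dim(W)[1]; F <- dim(W)[3]
  out <- matrix(0, L, F)
  for (l in seq_len(L)) {
    for (f in seq_len(F)) {
      acc <- b[f]
      for (m in seq_len(M)) {
        pos <- l + m - 1L
        if (pos <= L) acc <- acc + sum(W[m, , f] * X[pos, ])
      }
      out[l, f] <- max(acc, 0)
    }
  }
  out
}

oracle_maxpool <- function(Y, S1, S2) {
  L <- nrow(Y)
  Lp <- (L - S1) %/% S2 + 1L
  out <- matrix(0, Lp, ncol(Y))
  for (l in seq_len(Lp)) {
    for (f in seq_len(ncol(Y))) {
      best <- -Inf
      for (s in seq_len(S1)) best <- max(best, Y[(l - 1L) * S2 + s, f])
      out[l, f] <- best
    }
  }
  out
}

oracle_bn <- function(x, bn, eps) {
  if (is.matrix(x)) {
    out <- x
    for (f in seq_len(ncol(x)))
      out[, f] <- bn$scale[f] * (x[, f] - bn$mean[f]) /
        sqrt(bn$var[f] + eps) + bn$shift[f]
    out
  } else {
    vapply(seq_along(x), function(f)
      bn$scale[f] * (x[f] - bn$mean[f]) / sqrt(bn$var[f] + eps) + bn$shift[f],
      numeric(1))
  }
}

oracle_gap <- function(Y) {
  vapply(seq_len(ncol(Y)), function(f) sum(Y[, f]) / nrow(Y), numeric(1))
}

oracle_dense <- function(x, W, b, act) {
  if (!is.matrix(W)) W <- matrix(W, nrow = 1)
  out <- numeric(nrow(W))
  for (r in seq_len(nrow(W))) {
    acc <- b[r]
    for (j in seq_along(x)) acc <- acc + W[r, j] * x[j]
    out[r] <- switch(act, relu = max(acc, 0),
                     sigmoid = 1 / (1 + exp(-acc)), acc)
  }
  out
}

# End-to-end inference-mode forward pass from the layer formulas.
oracle_forward <- function(config, weights, X) {
  v <- config$variant
  if (v == "kmer4") {
    feat <- as.numeric(X)
  } else {
    cur <- oracle_conv(X, weights$conv_W, weights$conv_b)
    if (!(v %in% "no_maxpool")) cur <- oracle_maxpool(cur, config$S1, config$S2)
    if (v != "no_bn") cur <- oracle_bn(cur, weights$bn1, config$bn_epsilon)
    # dropout is the identity at inference
    feat <- if (v == "no_globalpool") as.vector(t(cur)) else oracle_gap(cur)
  }
  h <- oracle_dense(feat, weights$dense1_W, weights$dense1_b, "relu")
  if (v != "no_bn") h <- oracle_bn(h, weights$bn2, config$bn_epsilon)
  oracle_dense(h, weights$dense2_W, weights$dense2_b, "sigmoid")
}

# Sliding-window k-mer counter with explicit ambiguity skipping.
oracle_kmer <- function(bases, k) {
  words <- Biostrings::mkAllStrings(c("A", "C", "G", "T"), k)
  counts <- stats::setNames(numeric(length(words)), words)
  n_valid <- 0L
  if (nchar(bases) >= k) {
    for (i in seq_len(nchar(bases) - k + 1L)) {
      w <- substr(bases, i, i + k - 1L)
      if (grepl("^[ACGT]+$", w)) {
        counts[w] <- counts[w] + 1
        n_valid <- n_valid + 1L
      }
    }
  }
  if (n_valid == 0L) counts else counts / n_valid
}

# AUC by exhaustive pairwise concordance (ties count 1/2).
oracle_auc <- function(scores, truth) {
  pos <- scores[truth == 1 | truth == "virulent"]
  neg <- scores[truth == 0 | truth == "temperate"]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# Exact two-sided rank-sum p-value by exhaustive enumeration of all
# C(n1+n2, n1) group assignments (distinct values assumed).
oracle_ranksum_p <- function(g1, g2) {
  n1 <- length(g1); n2 <- length(g2)
  all_v <- c(g1, g2)
  r <- rank(all_v)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(n1 + n2, n1)
  u_all <- apply(combos, 2, function(ix) sum(r[ix]) - n1 * (n1 + 1) / 2)
  p_le <- mean(u_all <= u_obs)
  p_ge <- mean(u_all >= u_obs)
  min(1, 2 * min(p_le, p_ge))
}

# Stationary distribution of a 4-state chain by eigen-analysis.
oracle_stationary <- function(transition) {
  e <- eigen(t(transition))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  v / sum(v)
}

# Random weights with non-trivial batch-normalization statistics, for
# forward-pass agreement tests.
rand_weights <- function(config) {
  w <- init_weights(config)
  rand_bn <- function(n) list(scale = runif(n, 0.5, 1.5),
                              shift = rnorm(n, 0, 0.3),
                              mean = rnorm(n, 0, 0.3),
                              var = runif(n, 0.3, 2))
  if (config$variant != "no_bn") {
    if (config$variant != "kmer4") w$bn1 <- rand_bn(config$F)
    w$bn2 <- rand_bn(config$R)
  }
  if (length(w$conv_b) > 0) w$conv_b <- rnorm(length(w$conv_b), 0, 0.2)
  w$dense1_b <- rnorm(length(w$dense1_b), 0, 0.2)
  w$dense2_b <- rnorm(1, 0, 0.2)
  w
}

rand_seq <- function(n, with_ambiguity = FALSE) {
  alph <- if (with_ambiguity) c("A", "C", "G", "T", "N") else c("A", "C", "G", "T")
  prob <- if (with_ambiguity) c(rep(0.24, 4), 0.04) else rep(0.25, 4)
  paste0(sample(alph, n, replace = TRUE, prob = prob), collapse = "")
}
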
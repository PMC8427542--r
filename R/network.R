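# Network architecture: configuration, per-layer reference operations in
# vectorized R, the composed forward pass, weight initialization and
# archive I/O. The C++ kernels in src/net.cpp implement the same
# computation for training and batched prediction; tests assert agreement
# between the two paths and an independent nested-loop oracle.

.variants <- c("full", "kmer4", "no_maxpool", "no_dropout",
               "no_globalpool", "no_bn")

#' Network configuration
#'
#' Hyperparameters of the per-length-group classifier. Defaults are the
#' published architecture: `F = 64` convolution kernels of width `M = 6`,
#' max-pooling size `S1 = 3` with stride `S2 = 3`, dropout proportion
#' `P = 0.3` and `R = 64` dense units. Batch-normalization internals
#' (`bn_epsilon`, `bn_momentum`) are standard inference-time running-moment
#' settings.
#'
#' Ablation variants drop exactly one component: `no_maxpool`,
#' `no_dropout`, `no_bn` (removes both normalization layers),
#' `no_globalpool` (replaces global average pooling by flattening) and
#' `kmer4` (replaces the one-hot/convolution front end with a 4-mer
#' frequency vector fed straight into the first dense layer).
#'
#' @param L Model input length in bp (400, 800, 1200 or 1800 for groups
#'   A-D; any `L >= M` is accepted).
#' @param F Number of convolution kernels.
#' @param M Kernel width in bp.
#' @param S1 Pooling window size.
#' @param S2 Pooling stride.
#' @param P Dropout proportion in `[0, 1)`.
#' @param R Units of the first dense layer.
#' @param bn_epsilon Batch-normalization variance floor.
#' @param bn_momentum Running-moment momentum.
#' @param variant One of `"full"`, `"kmer4"`, `"no_maxpool"`,
#'   `"no_dropout"`, `"no_globalpool"`, `"no_bn"`.
#' @param kmer_k Word length of the k-mer front end (variant `kmer4`).
#' @return An object of class `network_config`.
#' @export
network_config <- function(L, F = 64L, M = 6L, S1 = 3L, S2 = 3L, P = 0.3,
                           R = 64L, bn_epsilon = 1e-3, bn_momentum = 0.99,
                           variant = "full", kmer_k = 4L) {
  variant <- match.arg(variant, .variants)
  L <- as.integer(L); F <- as.integer(F); M <- as.integer(M)
  S1 <- as.integer(S1); S2 <- as.integer(S2); R <- as.integer(R)
  if (any(c(F, M, S1, S2, R) < 1L)) stop("F, M, S1, S2, R must be positive")
  if (P < 0 || P >= 1) stop("P must be in [0, 1)")
  if (L < M) stop("L must be at least the kernel width M")
  if (bn_epsilon <= 0) stop("bn_epsilon must be positive")
  cfg <- structure(list(L = L, F = F, M = M, S1 = S1, S2 = S2, P = P, R = R,
                        bn_epsilon = bn_epsilon, bn_momentum = bn_momentum,
                        variant = variant, kmer_k = as.integer(kmer_k)),
                   class = "network_config")
  if (cfg$variant != "kmer4" && cfg$L < cfg$S1 && .uses(cfg, "pool"))
    stop("L must be at least the pooling size S1")
  cfg
}

# Which components a variant uses.
.uses <- function(config, what) {
  v <- config$variant
  switch(what,
         conv = v != "kmer4",
         pool = !(v %in% c("kmer4", "no_maxpool")),
         bn = !(v %in% c("no_bn")),
         dropout = !(v %in% c("kmer4", "no_dropout")),
         gpool = !(v %in% c("kmer4", "no_globalpool")),
         stop("unknown component: ", what))
}

#' Pooled length of a configuration
#'
#' Number of complete pooling windows: `floor((L - S1)/S2) + 1`, which for
#' `S1 == S2` equals `floor(L/S2)`. A trailing window that would overrun
#' the sequence end is dropped.
#'
#' @param config A [network_config()].
#' @return Integer pooled length (equals `L` when pooling is disabled).
#' @export
pooled_length <- function(config) {
  if (!.uses(config, "pool")) return(config$L)
  as.integer((config$L - config$S1) %/% config$S2 + 1L)
}

# Input dimension of the first dense layer.
.dense1_input <- function(config) {
  if (!.uses(config, "conv")) return(4L^config$kmer_k)
  if (.uses(config, "gpool")) return(config$F)
  config$F * pooled_length(config)
}

#' Layer sequence of a configuration variant
#'
#' @param config A [network_config()].
#' @return Character vector of layer names in forward order; the full
#'   variant is the eight-layer stack.
#' @export
build_variant <- function(config) {
  stopifnot(inherits(config, "network_config"))
  layers <- c(
    if (.uses(config, "conv")) "conv1d" else "kmer_input",
    if (.uses(config, "pool")) "maxpool",
    if (.uses(config, "bn")) "bn1",
    if (.uses(config, "dropout")) "dropout",
    if (.uses(config, "gpool")) "global_avg_pool"
    else if (.uses(config, "conv")) "flatten",
    "dense1",
    if (.uses(config, "bn")) "bn2",
    "dense2")
  if (!.uses(config, "conv"))
    layers <- setdiff(layers, c("maxpool", "bn1", "dropout",
                                "global_avg_pool", "flatten"))
  layers
}

#' @export
print.network_config <- function(x, ...) {
  cat("Network configuration (variant: ", x$variant, ")\n", sep = "")
  cat("  L=", x$L, " F=", x$F, " M=", x$M, " S1=", x$S1, " S2=", x$S2,
      " P=", x$P, " R=", x$R, "\n", sep = "")
  cat("  layers:", paste(build_variant(x), collapse = " -> "), "\n")
  invisible(x)
}

# ---------------------------------------------------------------------------
# Activations and per-layer reference operations
# ---------------------------------------------------------------------------

#' Rectified linear unit
#' @param x Numeric vector or matrix.
#' @return `x` where `x >= 0`, else 0, elementwise.
#' @export
relu <- function(x) {
  x[x < 0] <- 0
  x
}

#' Numerically stable logistic sigmoid
#' @param x Numeric vector.
#' @return `1 / (1 + exp(-x))`, computed stably for large `|x|`.
#' @export
sigmoid <- function(x) {
  out <- numeric(length(x))
  pos <- !is.na(x) & x >= 0
  out[pos] <- 1 / (1 + exp(-x[pos]))
  out[!pos] <- exp(x[!pos]) / (1 + exp(x[!pos]))
  out[is.na(x)] <- NA_real_
  if (is.matrix(x)) dim(out) <- dim(x)
  out
}

#' 1D convolution layer (reference implementation)
#'
#' Computes `Y[l, f] = ReLU(sum_{m,n} W[m, n, f] * X[l + m, n] + b[f])` for
#' `l = 0..L-1`, with `X` zero-padded on the right so the output length
#' stays `L`.
#'
#' @param X `L x 4` one-hot matrix.
#' @param conv_W `M x 4 x F` kernel array.
#' @param conv_b Length-`F` bias vector.
#' @return `L x F` matrix of rectified feature maps.
#' @export
conv1d_forward <- function(X, conv_W, conv_b) {
  stopifnot(is.matrix(X), ncol(X) == 4, length(dim(conv_W)) == 3,
            dim(conv_W)[2] == 4, length(conv_b) == dim(conv_W)[3])
  L <- nrow(X); M <- dim(conv_W)[1]; F <- dim(conv_W)[3]
  if (L < 1) stop("empty input")
  Xpad <- rbind(X, matrix(0, nrow = M - 1, ncol = 4))
  out <- matrix(rep(conv_b, each = L), nrow = L)
  for (m in seq_len(M)) {
    Wm <- matrix(conv_W[m, , ], nrow = 4, ncol = F)  # 4 x F
    out <- out + Xpad[m:(m + L - 1), , drop = FALSE] %*% Wm
  }
  relu(out)
}

#' 1D max pooling (reference implementation)
#'
#' Takes the maximum over windows of `S1` positions advanced by stride
#' `S2`, per channel; windows overrunning the end are dropped.
#'
#' @param Y `L x F` input matrix.
#' @param S1 Window size.
#' @param S2 Stride.
#' @return `L' x F` matrix with `L' = floor((L - S1)/S2) + 1`.
#' @export
maxpool1d <- function(Y, S1, S2) {
  stopifnot(is.matrix(Y), S1 >= 1, S2 >= 1)
  L <- nrow(Y)
  if (L < S1) stop("input length ", L, " is shorter than the pooling size ", S1)
  Lp <- (L - S1) %/% S2 + 1L
  out <- matrix(NA_real_, nrow = Lp, ncol = ncol(Y))
  for (l in seq_len(Lp)) {
    rows <- ((l - 1L) * S2 + 1L):((l - 1L) * S2 + S1)
    out[l, ] <- apply(Y[rows, , drop = FALSE], 2, max)
  }
  out
}

#' Batch normalization at inference (reference implementation)
#'
#' `out = scale * (x - mean) / sqrt(var + epsilon) + shift` per channel,
#' using running moments accumulated during training.
#'
#' @param x Numeric vector (one value per channel) or `L x F` matrix
#'   (channels in columns).
#' @param bn List with fields `scale`, `shift`, `mean`, `var`.
#' @param epsilon Variance floor.
#' @return Same shape as `x`.
#' @export
batchnorm_inference <- function(x, bn, epsilon = 1e-3) {
  stopifnot(all(c("scale", "shift", "mean", "var") %in% names(bn)),
            all(bn$var >= 0))
  scl <- bn$scale / sqrt(bn$var + epsilon)
  if (is.matrix(x)) {
    sweep(sweep(x, 2, bn$mean, "-"), 2, scl, "*") +
      matrix(rep(bn$shift, each = nrow(x)), nrow = nrow(x))
  } else {
    bn$shift + scl * (x - bn$mean)
  }
}

#' Dropout (training mode)
#'
#' Multiplies by a Bernoulli keep mask and rescales kept activations by
#' `1/(1-P)` (inverted dropout), so inference is the identity. Draws from
#' R's RNG.
#'
#' @param x Numeric vector or matrix.
#' @param P Drop proportion in `[0, 1)`.
#' @param mode `"train"` applies the mask; `"infer"` is the identity.
#' @return List with `values` and the applied `mask`.
#' @export
dropout_train <- function(x, P, mode = c("train", "infer")) {
  mode <- match.arg(mode)
  if (P < 0 || P >= 1) stop("P must be in [0, 1)")
  if (mode == "infer" || P == 0) {
    mask <- x; mask[] <- 1
    return(list(values = x, mask = mask))
  }
  keep <- runif(length(x)) >= P
  mask <- x
  mask[] <- ifelse(keep, 1 / (1 - P), 0)
  list(values = x * mask, mask = mask)
}

#' Global average pooling (reference implementation)
#' @param Y `L' x F` matrix.
#' @return Length-`F` vector of per-channel means.
#' @export
global_avg_pool <- function(Y) {
  stopifnot(is.matrix(Y))
  if (nrow(Y) < 1) stop("empty input")
  colMeans(Y)
}

#' Dense layer (reference implementation)
#' @param x Input vector.
#' @param W Weight matrix (`units x length(x)`) or vector for a single
#'   output unit.
#' @param b Bias vector (or scalar).
#' @param activation `"relu"`, `"sigmoid"` or `"linear"`.
#' @return Output vector (scalar for a single unit).
#' @export
dense_forward <- function(x, W, b, activation = c("relu", "sigmoid", "linear")) {
  activation <- match.arg(activation)
  if (!is.matrix(W)) W <- matrix(W, nrow = 1)
  if (ncol(W) != length(x)) stop("weight/input shape mismatch")
  if (nrow(W) != length(b)) stop("weight/bias shape mismatch")
  z <- drop(W %*% x + b)
  switch(activation, relu = relu(z), sigmoid = sigmoid(z), linear = z)
}

#' Composed forward pass (reference implementation)
#'
#' Runs the configured layer stack on one padded one-hot matrix. Inference
#' mode is deterministic (batch normalization uses running moments and
#' dropout is the identity); training mode draws a dropout mask from R's
#' RNG. This is the readable reference path; batched prediction and
#' training use the compiled kernels, which tests hold to agreement with
#' this function and with an independent nested-loop oracle.
#'
#' @param config A [network_config()].
#' @param weights A weight list from [init_weights()] or a trained model.
#' @param X `L x 4` one-hot matrix (pad with [one_hot_encode()]'s
#'   `target_length = config$L`); for variant `kmer4`, a `4^k` frequency
#'   vector.
#' @param mode `"infer"` or `"train"`.
#' @param trace If `TRUE`, also return every intermediate activation.
#' @return List with `score` in (0,1) and, if requested, `trace`.
#' @export
forward <- function(config, weights, X, mode = c("infer", "train"),
                    trace = FALSE) {
  mode <- match.arg(mode)
  stopifnot(inherits(config, "network_config"))
  tr <- list()
  if (.uses(config, "conv")) {
    stopifnot(is.matrix(X), nrow(X) == config$L)
    cur <- conv1d_forward(X, weights$conv_W, weights$conv_b)
    tr$Y_C <- cur
    if (.uses(config, "pool")) {
      cur <- maxpool1d(cur, config$S1, config$S2)
      tr$Y_M <- cur
    }
    if (.uses(config, "bn")) {
      cur <- batchnorm_inference(cur, weights$bn1, config$bn_epsilon)
      tr$Y_B1 <- cur
    }
    if (.uses(config, "dropout")) {
      dp <- dropout_train(cur, config$P, mode = mode)
      cur <- dp$values
      tr$Y_Dp <- cur
      tr$K <- dp$mask
    }
    feat <- if (.uses(config, "gpool")) global_avg_pool(cur) else as.vector(t(cur))
    tr$y_G <- feat
  } else {
    feat <- as.numeric(X)
    if (length(feat) != 4^config$kmer_k)
      stop("kmer4 variant expects a ", 4^config$kmer_k, "-long feature vector")
  }
  h <- dense_forward(feat, weights$dense1_W, weights$dense1_b, "relu")
  tr$y_D1 <- h
  if (.uses(config, "bn")) {
    h <- batchnorm_inference(h, weights$bn2, config$bn_epsilon)
    tr$y_B2 <- h
  }
  score <- dense_forward(h, weights$dense2_W, weights$dense2_b, "sigmoid")
  tr$y_D2 <- score
  if (trace) list(score = score, trace = tr) else list(score = score)
}

# ---------------------------------------------------------------------------
# Weights
# ---------------------------------------------------------------------------

#' Initialize network weights
#'
#' Glorot-uniform initialization for convolution and dense weights, zero
#' biases, and identity batch-normalization parameters (scale 1, shift 0,
#' running mean 0, running variance 1).
#'
#' @param config A [network_config()].
#' @param seed Optional integer for a deterministic, RNG-state-preserving
#'   draw.
#' @return A weight list of class `layer_weights` with fields `conv_W`
#'   (`M x 4 x F`), `conv_b`, `bn1`, `dense1_W`, `dense1_b`, `bn2`,
#'   `dense2_W`, `dense2_b`. Fields unused by the variant are empty.
#' @export
init_weights <- function(config, seed = NULL) {
  stopifnot(inherits(config, "network_config"))
  glorot <- function(fan_in, fan_out, n) {
    lim <- sqrt(6 / (fan_in + fan_out))
    runif(n, -lim, lim)
  }
  gen <- function() {
    w <- list()
    if (.uses(config, "conv")) {
      w$conv_W <- array(glorot(config$M * 4, config$M * config$F,
                               config$M * 4 * config$F),
                        dim = c(config$M, 4, config$F))
      w$conv_b <- numeric(config$F)
      w$bn1 <- .bn_identity(if (.uses(config, "bn")) config$F else 0L)
    } else {
      w$conv_W <- array(numeric(0), dim = c(0, 4, 0))
      w$conv_b <- numeric(0)
      w$bn1 <- .bn_identity(0L)
    }
    din <- .dense1_input(config)
    w$dense1_W <- matrix(glorot(din, config$R, config$R * din),
                         nrow = config$R, ncol = din)
    w$dense1_b <- numeric(config$R)
    w$bn2 <- .bn_identity(if (.uses(config, "bn")) config$R else 0L)
    w$dense2_W <- glorot(config$R, 1, config$R)
    w$dense2_b <- 0
    structure(w, class = "layer_weights")
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

.bn_identity <- function(n) {
  list(scale = rep(1, n), shift = rep(0, n),
       mean = rep(0, n), var = rep(1, n))
}

# Flatten weights into the layout the C++ kernels expect. conv_Wf is
# F x (M*4); column index m*4 + n holds kernel position m, one-hot column n.
.weights_to_cpp <- function(weights) {
  W <- weights$conv_W
  if (length(W) > 0) {
    M <- dim(W)[1]; F <- dim(W)[3]
    wf <- t(matrix(aperm(W, c(2, 1, 3)), nrow = 4 * M, ncol = F))
  } else {
    wf <- matrix(0, nrow = 0, ncol = 0)
  }
  list(conv_Wf = wf, conv_b = as.numeric(weights$conv_b),
       bn1_scale = as.numeric(weights$bn1$scale),
       bn1_shift = as.numeric(weights$bn1$shift),
       bn1_mean = as.numeric(weights$bn1$mean),
       bn1_var = as.numeric(weights$bn1$var),
       dense1_W = weights$dense1_W,
       dense1_b = as.numeric(weights$dense1_b),
       bn2_scale = as.numeric(weights$bn2$scale),
       bn2_shift = as.numeric(weights$bn2$shift),
       bn2_mean = as.numeric(weights$bn2$mean),
       bn2_var = as.numeric(weights$bn2$var),
       dense2_W = as.numeric(weights$dense2_W),
       dense2_b = as.numeric(weights$dense2_b))
}

.weights_from_cpp <- function(cw, config) {
  w <- list()
  if (.uses(config, "conv")) {
    M <- config$M; F <- config$F
    w$conv_W <- aperm(array(t(cw$conv_Wf), dim = c(4, M, F)), c(2, 1, 3))
    w$conv_b <- as.numeric(cw$conv_b)
  } else {
    w$conv_W <- array(numeric(0), dim = c(0, 4, 0))
    w$conv_b <- numeric(0)
  }
  w$bn1 <- list(scale = as.numeric(cw$bn1_scale), shift = as.numeric(cw$bn1_shift),
                mean = as.numeric(cw$bn1_mean), var = as.numeric(cw$bn1_var))
  w$dense1_W <- cw$dense1_W
  w$dense1_b <- as.numeric(cw$dense1_b)
  w$bn2 <- list(scale = as.numeric(cw$bn2_scale), shift = as.numeric(cw$bn2_shift),
                mean = as.numeric(cw$bn2_mean), var = as.numeric(cw$bn2_var))
  w$dense2_W <- as.numeric(cw$dense2_W)
  w$dense2_b <- as.numeric(cw$dense2_b)
  structure(w, class = "layer_weights")
}

# Flag list for the C++ kernels.
.conf_for_cpp <- function(config) {
  list(L = config$L, F = config$F, M = config$M, S1 = config$S1,
       S2 = config$S2, R = config$R, K = 4L^config$kmer_k, P = config$P,
       bn_epsilon = config$bn_epsilon, bn_momentum = config$bn_momentum,
       use_conv = .uses(config, "conv"), use_pool = .uses(config, "pool"),
       use_bn = .uses(config, "bn"), use_dropout = .uses(config, "dropout"),
       use_gpool = .uses(config, "gpool"))
}

# Batched inference with the compiled kernels. `sequences` is a character
# vector (conv front end) or an n x 4^k feature matrix (kmer front end).
.score_batch <- function(sequences, config, weights) {
  cw <- .weights_to_cpp(weights)
  cf <- .conf_for_cpp(config)
  if (.uses(config, "conv")) {
    codes <- .encode_batch(sequences, config$L)
    as.numeric(cpp_forward_batch(codes, matrix(0, 0, 0), cw, cf))
  } else {
    feat <- t(as.matrix(sequences))  # K x n
    as.numeric(cpp_forward_batch(matrix(0L, 0, 0), feat, cw, cf))
  }
}

.WEIGHTS_FORMAT_VERSION <- 1L

#' Save a weight archive
#'
#' Serializes all tensors plus the configuration into a versioned archive
#' (one file per length group).
#'
#' @param weights A `layer_weights` list.
#' @param config The matching [network_config()].
#' @param path Output path (conventionally `.rds`).
#' @return `path`, invisibly.
#' @export
save_weights <- function(weights, config, path) {
  stopifnot(inherits(config, "network_config"))
  saveRDS(list(format_version = .WEIGHTS_FORMAT_VERSION,
               config = config, weights = weights), file = path)
  invisible(path)
}

#' Load a weight archive
#'
#' @param path Path written by [save_weights()].
#' @return List with `config` and `weights`. A corrupted file or a
#'   mismatched format version raises an explicit error.
#' @export
load_weights <- function(path) {
  obj <- tryCatch(readRDS(path), error = function(e)
    stop("corrupted or unreadable weight archive: ", path,
         " (", conditionMessage(e), ")", call. = FALSE))
  if (!is.list(obj) || is.null(obj$format_version) ||
      !identical(as.integer(obj$format_version), .WEIGHTS_FORMAT_VERSION))
    stop("weight archive version mismatch in ", path, ": expected ",
         .WEIGHTS_FORMAT_VERSION, ", found ",
         if (is.list(obj)) obj$format_version %||% "none" else "none")
  if (!inherits(obj$config, "network_config") || !is.list(obj$weights))
    stop("weight archive ", path, " is missing config or weights")
  obj[c("config", "weights")]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
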
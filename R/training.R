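# Model fitting: one network per length group, trained with Adam on
# binary cross-entropy, early-stopped on a genome-disjoint validation
# split. The returned "phage_cnn" object is the package's fitted-model
# class, with the usual print/summary/coef/predict/plot methods.

#' Training specification
#'
#' Optimizer and schedule settings. The optimizer is Adam with learning
#' rate `1e-4`, the loss is binary cross-entropy and the batch size is 32
#' (the published training settings). Epoch count and early stopping are
#' not part of the published settings; the defaults bound training with a
#' principled stop on validation loss.
#'
#' @param learning_rate Adam learning rate (> 0).
#' @param batch_size Minibatch size (>= 1).
#' @param max_epochs Maximum training epochs.
#' @param patience Early-stopping patience (epochs without validation-loss
#'   improvement).
#' @param validation_fraction Fraction of training *genomes* (not
#'   fragments) held out for validation, in (0, 0.5).
#' @param seed Integer seed governing weight initialization, the
#'   validation split, epoch shuffles and dropout masks.
#' @return An object of class `train_spec`.
#' @export
train_spec <- function(learning_rate = 1e-4, batch_size = 32L,
                       max_epochs = 100L, patience = 10L,
                       validation_fraction = 0.1, seed = 1L) {
  if (learning_rate <= 0) stop("learning_rate must be positive")
  if (batch_size < 1) stop("batch_size must be >= 1")
  if (validation_fraction <= 0 || validation_fraction >= 0.5)
    stop("validation_fraction must be in (0, 0.5)")
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 validation_fraction = validation_fraction,
                 seed = as.integer(seed)),
            class = "train_spec")
}

#' Binary cross-entropy loss
#'
#' `-(y * log(s) + (1 - y) * log(1 - s))`, with scores clipped into
#' `[eps, 1 - eps]`.
#'
#' @param score Predicted scores in (0, 1).
#' @param label Binary labels (1 = virulent, 0 = temperate).
#' @param eps Clipping bound.
#' @return Elementwise losses (>= 0); take `mean()` for a batch loss.
#' @export
bce_loss <- function(score, label, eps = 1e-7) {
  s <- pmin(pmax(score, eps), 1 - eps)
  -(label * log(s) + (1 - label) * log(1 - s))
}

#' Fit a phage lifestyle classifier on fragments of one length group
#'
#' Trains the configured network on labelled fragments (virulent = positive
#' class) with Adam, binary cross-entropy and minibatches, holding out a
#' genome-disjoint validation split for early stopping: validation genomes
#' contribute no fragments to the gradient updates, mirroring the
#' genome-level test-fold rule. Deterministic given `spec$seed` under the
#' single-threaded contract.
#'
#' @param fragments Data frame of labelled fragments with columns `bases`,
#'   `lifestyle`, `genome_id` (e.g. from [build_benchmark()]); all
#'   fragments must fit the configured input length.
#' @param config A [network_config()]; `config$L` must cover the longest
#'   fragment.
#' @param spec A [train_spec()].
#' @return An object of class `phage_cnn`: a list with the trained
#'   `weights`, `config`, `spec`, a per-epoch `log` data frame
#'   (`train_loss`, `val_loss`, `val_acc`), `best_epoch`, the validation
#'   genome ids and the wall time in seconds.
#' @export
train_model <- function(fragments, config, spec = train_spec()) {
  stopifnot(inherits(config, "network_config"), inherits(spec, "train_spec"),
            is.data.frame(fragments),
            all(c("bases", "lifestyle", "genome_id") %in% names(fragments)))
  if (nrow(fragments) == 0L) stop("no fragments to train on")
  classes <- unique(fragments$lifestyle)
  if (!setequal(classes, c("virulent", "temperate")))
    stop("training requires both classes; found only: ",
         paste(classes, collapse = ", "))
  t0 <- proc.time()[["elapsed"]]

  y <- as.numeric(fragments$lifestyle == "virulent")
  fit <- withr::with_seed(spec$seed, {
    weights0 <- init_weights(config)
    val_gen <- .validation_genomes(fragments, spec$validation_fraction)
    is_val <- fragments$genome_id %in% val_gen
    if (.uses(config, "conv")) {
      codes <- .encode_batch(fragments$bases, config$L)
      feat <- matrix(0, 0, 0)
    } else {
      codes <- matrix(0L, 0, 0)
      feat <- t(vapply(fragments$bases,
                       function(b) kmer_frequencies(b, config$kmer_k),
                       numeric(4^config$kmer_k), USE.NAMES = FALSE))
      feat <- t(feat)  # K x n
    }
    res <- cpp_train_network(
      codes, feat, y, .weights_to_cpp(weights0), .conf_for_cpp(config),
      list(learning_rate = spec$learning_rate, batch_size = spec$batch_size,
           max_epochs = spec$max_epochs, patience = spec$patience),
      which(!is_val), which(is_val))
    list(res = res, val_gen = val_gen, n_val = sum(is_val))
  })
  res <- fit$res
  log <- data.frame(epoch = seq_along(res$train_loss),
                    train_loss = as.numeric(res$train_loss),
                    val_loss = as.numeric(res$val_loss),
                    val_acc = as.numeric(res$val_acc))
  structure(list(weights = .weights_from_cpp(res$weights, config),
                 config = config, spec = spec, log = log,
                 best_epoch = res$best_epoch,
                 n_train = nrow(fragments) - fit$n_val, n_val = fit$n_val,
                 val_genomes = fit$val_gen,
                 classes = c(positive = "virulent", negative = "temperate"),
                 wall_time = proc.time()[["elapsed"]] - t0),
            class = "phage_cnn")
}

# Pick validation genomes stratified by lifestyle; never strip a class of
# all its training genomes.
.validation_genomes <- function(fragments, fraction) {
  out <- character(0)
  for (cls in c("virulent", "temperate")) {
    ids <- unique(fragments$genome_id[fragments$lifestyle == cls])
    nv <- min(max(1L, floor(fraction * length(ids))), length(ids) - 1L)
    if (nv > 0) out <- c(out, sample(ids, nv))
  }
  out
}

#' @export
print.phage_cnn <- function(x, ...) {
  cat("Phage lifestyle classifier (", x$config$variant, " variant, L = ",
      x$config$L, " bp)\n", sep = "")
  cat("  trained on ", x$n_train, " fragments (+", x$n_val,
      " genome-disjoint validation), ", nrow(x$log), " epochs, best epoch ",
      x$best_epoch, "\n", sep = "")
  best <- x$log[x$best_epoch, ]
  if (is.finite(best$val_acc))
    cat(sprintf("  validation loss %.4f, accuracy %.3f\n",
                best$val_loss, best$val_acc))
  invisible(x)
}

#' @export
summary.phage_cnn <- function(object, ...) {
  out <- list(config = object$config, best_epoch = object$best_epoch,
              epochs_run = nrow(object$log),
              log = object$log, n_train = object$n_train,
              n_val = object$n_val, wall_time = object$wall_time)
  class(out) <- "summary.phage_cnn"
  out
}

#' @export
print.summary.phage_cnn <- function(x, ...) {
  print(x$config)
  cat(sprintf("epochs run: %d (best %d); %d train / %d validation fragments; %.1f s\n",
              x$epochs_run, x$best_epoch, x$n_train, x$n_val, x$wall_time))
  print(utils::tail(x$log, 5), row.names = FALSE)
  invisible(x)
}

#' @export
coef.phage_cnn <- function(object, ...) object$weights

#' Plot training curves of a fitted classifier
#' @param x A `phage_cnn` object.
#' @param ... Passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.phage_cnn <- function(x, ...) {
  graphics::matplot(x$log$epoch, cbind(x$log$train_loss, x$log$val_loss),
                    type = "l", lty = 1:2, col = c("black", "red"),
                    xlab = "epoch", ylab = "binary cross-entropy", ...)
  graphics::abline(v = x$best_epoch, lty = 3)
  graphics::legend("topright", c("train", "validation"), lty = 1:2,
                   col = c("black", "red"), bty = "n")
  invisible(x)
}

#' Score sequences with a single-group fitted model
#'
#' Pads each sequence to the model's input length and runs the inference
#' forward pass. Sequences longer than `config$L` are rejected; use
#' [route_and_score()] for arbitrary-length input.
#'
#' @param object A `phage_cnn` model.
#' @param newdata Character vector of sequences, or a data frame with a
#'   `bases` column.
#' @param type `"score"` for numeric scores in (0, 1), `"label"` for
#'   cut-off-free labels.
#' @param ... Unused.
#' @return Numeric scores or character labels, one per sequence.
#' @export
predict.phage_cnn <- function(object, newdata, type = c("score", "label"), ...) {
  type <- match.arg(type)
  bases <- if (is.data.frame(newdata)) newdata$bases else newdata
  stopifnot(is.character(bases))
  if (.uses(object$config, "conv")) {
    scores <- .score_batch(bases, object$config, object$weights)
  } else {
    feat <- t(vapply(bases, function(b) kmer_frequencies(b, object$config$kmer_k),
                     numeric(4^object$config$kmer_k), USE.NAMES = FALSE))
    scores <- .score_batch(feat, object$config, object$weights)
  }
  if (type == "score") scores else classify(scores, cutoff_policy(0))
}

#' Train one model per length group
#'
#' @param corpora Named list with fragment data frames for groups
#'   `"A"`-`"D"` (every group must be present and non-empty).
#' @param spec A [train_spec()] applied to every group.
#' @param config_args Named list of [network_config()] overrides applied
#'   to every group (e.g. `list(variant = "no_bn")`); `L` is always the
#'   group's input length.
#' @return A named list of `phage_cnn` models of class `phage_model_set`.
#' @export
train_all_groups <- function(corpora, spec = train_spec(),
                             config_args = list()) {
  lg <- length_groups()
  missing_groups <- setdiff(lg$name, names(corpora))
  if (length(missing_groups) > 0)
    stop("missing fragment corpus for group(s): ",
         paste(missing_groups, collapse = ", "))
  models <- lapply(lg$name, function(g) {
    frags <- corpora[[g]]
    if (is.null(frags) || nrow(frags) == 0L)
      stop("empty fragment corpus for group ", g)
    cfg <- do.call(network_config, c(list(L = lg$L[lg$name == g]), config_args))
    train_model(frags, cfg, spec)
  })
  names(models) <- lg$name
  structure(models, class = "phage_model_set")
}

#' @export
print.phage_model_set <- function(x, ...) {
  cat("Phage lifestyle model set:\n")
  for (g in names(x))
    cat(sprintf("  group %s: L = %d bp, best epoch %d\n",
                g, x[[g]]$config$L, x[[g]]$best_epoch))
  invisible(x)
}

#' Save a model set as per-group weight archives plus a manifest
#'
#' @param models A `phage_model_set`.
#' @param dir Output directory (created if needed); writes `<group>.rds`
#'   archives and `manifest.json` mapping group name to archive.
#' @return The manifest path, invisibly.
#' @export
save_model_set <- function(models, dir) {
  stopifnot(inherits(models, "phage_model_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  entries <- list()
  for (g in names(models)) {
    fn <- paste0(g, ".rds")
    save_weights(models[[g]]$weights, models[[g]]$config, file.path(dir, fn))
    entries[[g]] <- fn
  }
  manifest <- file.path(dir, "manifest.json")
  jsonlite::write_json(list(format_version = .WEIGHTS_FORMAT_VERSION,
                            groups = entries),
                       manifest, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Load a model set saved by [save_model_set()]
#'
#' @param dir Directory containing `manifest.json` and the archives.
#' @return A `phage_model_set` (models carry weights and config; training
#'   logs are not part of the archive).
#' @export
load_model_set <- function(dir) {
  manifest <- file.path(dir, "manifest.json")
  if (!file.exists(manifest)) stop("no manifest.json in ", dir)
  mf <- jsonlite::read_json(manifest)
  if (!identical(as.integer(mf$format_version), .WEIGHTS_FORMAT_VERSION))
    stop("manifest version mismatch in ", manifest)
  models <- lapply(mf$groups, function(fn) {
    obj <- load_weights(file.path(dir, fn))
    structure(list(weights = obj$weights, config = obj$config,
                   log = data.frame(), best_epoch = NA_integer_),
              class = "phage_cnn")
  })
  structure(models, class = "phage_model_set")
}
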
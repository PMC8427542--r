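# Performance metrics and the genome-level cross-validation experiment.

#' Confusion counts over labelled predictions
#'
#' Virulent is the positive class. Records labelled `"uncertain"` are
#' excluded from the counts and reported separately.
#'
#' @param truth Character vector of true lifestyles
#'   (`virulent`/`temperate`).
#' @param predicted Character vector of predicted labels
#'   (`virulent`/`temperate`/`uncertain`).
#' @return An object of class `confusion_counts` with fields `TP`, `FP`,
#'   `TN`, `FN` and `n_uncertain_excluded`.
#' @export
confusion <- function(truth, predicted) {
  stopifnot(length(truth) == length(predicted),
            all(truth %in% c("virulent", "temperate")),
            all(predicted %in% c("virulent", "temperate", "uncertain")))
  keep <- predicted != "uncertain"
  if (!any(keep)) stop("all predictions are uncertain; no counts to compute")
  t2 <- truth[keep]; p2 <- predicted[keep]
  structure(list(TP = sum(t2 == "virulent" & p2 == "virulent"),
                 FP = sum(t2 == "temperate" & p2 == "virulent"),
                 TN = sum(t2 == "temperate" & p2 == "temperate"),
                 FN = sum(t2 == "virulent" & p2 == "temperate"),
                 n_uncertain_excluded = sum(!keep)),
            class = "confusion_counts")
}

#' Sensitivity, specificity and accuracy
#'
#' `Sn = TP/(TP + FN)`, `Sp = TN/(TN + FP)`,
#' `Acc = (TP + TN)/(TP + TN + FN + FP)`. Sensitivity is virulent recall
#' and specificity temperate recall. A metric with a zero denominator is
#' returned as `NA` with a warning.
#'
#' @param counts A `confusion_counts` object, or a list with fields `TP`,
#'   `FP`, `TN`, `FN`.
#' @return Named numeric vector `c(Sn, Sp, Acc)`.
#' @export
metrics <- function(counts) {
  stopifnot(all(c("TP", "FP", "TN", "FN") %in% names(counts)))
  with(counts, {
    total <- TP + TN + FP + FN
    if (total == 0) stop("no counted predictions")
    sn <- if (TP + FN > 0) TP / (TP + FN) else {
      warning("no virulent records; Sn undefined"); NA_real_ }
    sp <- if (TN + FP > 0) TN / (TN + FP) else {
      warning("no temperate records; Sp undefined"); NA_real_ }
    c(Sn = sn, Sp = sp, Acc = (TP + TN) / total)
  })
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("TP=%d FP=%d TN=%d FN=%d (uncertain excluded: %d)\n",
              x$TP, x$FP, x$TN, x$FN, x$n_uncertain_excluded))
  invisible(x)
}

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney U statistic normalized by
#' `n_pos * n_neg`; tied scores contribute 1/2. Exact, tie-aware, and
#' invariant under any strictly monotone transform of the scores.
#'
#' @param scores Numeric scores.
#' @param truth True lifestyles (`virulent` = positive) or 0/1 labels.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, truth) {
  if (is.character(truth)) truth <- as.numeric(truth == "virulent")
  stopifnot(length(scores) == length(truth), all(truth %in% c(0, 1)))
  npos <- sum(truth == 1); nneg <- sum(truth == 0)
  if (npos == 0 || nneg == 0)
    stop("AUC requires both classes to be present")
  r <- rank(scores)
  (sum(r[truth == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Run the genome-level cross-validation experiment
#'
#' For every fold and length group: builds a leakage-free fragment
#' benchmark, trains a model, predicts the held-out fragments (cut-off
#' free, `t = 0`) and computes Sn/Sp/Acc/AUC; aggregates mean and SD per
#' group across folds. Each fold x group run re-audits genome disjointness.
#'
#' @param genomes Data frame with `id`, `bases`.
#' @param labels Label table.
#' @param plan A `cv_fold_plan`.
#' @param groups Length groups to evaluate (default all four).
#' @param n_train,n_test Fragment counts per fold x group.
#' @param spec A [train_spec()]; each fold uses `spec$seed + fold` so the
#'   rotations differ while the whole run stays deterministic.
#' @param config_args Named list of [network_config()] overrides.
#' @param seed Seed for fragment extraction.
#' @return An object of class `cv_report` with `results` (one row per
#'   fold x group) and `summary` (mean +/- SD per group).
#' @export
run_cross_validation <- function(genomes, labels, plan,
                                 groups = c("A", "B", "C", "D"),
                                 n_train = 8000L, n_test = 2000L,
                                 spec = train_spec(), config_args = list(),
                                 seed = 1L) {
  stopifnot(inherits(plan, "cv_fold_plan"))
  lg <- length_groups()
  rows <- list()
  for (fold in seq_len(plan$n_folds)) {
    for (g in groups) {
      bench <- build_benchmark(genomes, labels, plan, fold, g,
                               n_train = n_train, n_test = n_test,
                               seed = seed + 131L * fold + match(g, lg$name))
      leaked <- intersect(unique(bench$train$genome_id),
                          unique(bench$test$genome_id))
      if (length(leaked) > 0)
        stop("fold ", fold, " group ", g, ": genome leakage: ",
             paste(leaked, collapse = ", "))
      spec_fold <- spec
      spec_fold$seed <- spec$seed + fold
      cfg <- do.call(network_config, c(list(L = lg$L[lg$name == g]),
                                       config_args))
      model <- train_model(bench$train, cfg, spec_fold)
      scores <- predict(model, bench$test$bases)
      labels_hat <- classify(scores, cutoff_policy(0))
      cm <- confusion(bench$test$lifestyle, labels_hat)
      m <- metrics(cm)
      rows[[length(rows) + 1L]] <- data.frame(
        fold = fold, group = g, Sn = m[["Sn"]], Sp = m[["Sp"]],
        Acc = m[["Acc"]], AUC = roc_auc(scores, bench$test$lifestyle),
        n_uncertain = cm$n_uncertain_excluded, n_test = nrow(bench$test),
        stringsAsFactors = FALSE)
    }
  }
  results <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(split(results, results$group), function(d) {
    data.frame(group = d$group[1],
               Sn_mean = mean(d$Sn), Sn_sd = sd(d$Sn),
               Sp_mean = mean(d$Sp), Sp_sd = sd(d$Sp),
               Acc_mean = mean(d$Acc), Acc_sd = sd(d$Acc),
               AUC_mean = mean(d$AUC), n_folds = nrow(d),
               stringsAsFactors = FALSE)
  }))
  rownames(agg) <- NULL
  structure(list(results = results, summary = agg), class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat("Genome-level cross-validation report\n")
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  group %s: Acc %.3f +/- %.3f, Sn %.3f, Sp %.3f, AUC %.3f (%d folds)\n",
                s$group[i], s$Acc_mean[i], s$Acc_sd[i], s$Sn_mean[i],
                s$Sp_mean[i], s$AUC_mean[i], s$n_folds[i]))
  invisible(x)
}

#' Ablation comparison on a fixed benchmark
#'
#' Trains each architecture variant on the same training fragments with
#' the same seeds and evaluates on the same test fragments.
#'
#' @param benchmark List with `train` and `test` fragment data frames
#'   (e.g. from [build_benchmark()]).
#' @param variants Subset of the six variants (default all).
#' @param config A [network_config()] template; each run keeps its `L` and
#'   hyperparameters, changing only the variant.
#' @param spec A [train_spec()] shared by every variant.
#' @return Data frame with one row per variant: `variant`, `Sn`, `Sp`,
#'   `Acc`, `AUC`.
#' @export
run_ablation <- function(benchmark, variants = .variants, config,
                         spec = train_spec()) {
  stopifnot(all(variants %in% .variants),
            inherits(config, "network_config"))
  rows <- lapply(variants, function(v) {
    cfg <- network_config(L = config$L, F = config$F, M = config$M,
                          S1 = config$S1, S2 = config$S2, P = config$P,
                          R = config$R, bn_epsilon = config$bn_epsilon,
                          bn_momentum = config$bn_momentum, variant = v,
                          kmer_k = config$kmer_k)
    model <- train_model(benchmark$train, cfg, spec)
    scores <- predict(model, benchmark$test$bases)
    m <- metrics(confusion(benchmark$test$lifestyle,
                           classify(scores, cutoff_policy(0))))
    data.frame(variant = v, Sn = m[["Sn"]], Sp = m[["Sp"]], Acc = m[["Acc"]],
               AUC = roc_auc(scores, benchmark$test$lifestyle),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
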
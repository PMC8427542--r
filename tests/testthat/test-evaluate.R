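test_that("confusion counts treat virulent as positive and exclude uncertain", {
  truth <- rep(c("virulent", "temperate"), each = 10)
  cm <- confusion(truth, truth)
  expect_equal(cm$TP, 10); expect_equal(cm$TN, 10)
  expect_equal(cm$FP, 0); expect_equal(cm$FN, 0)

  all_vir <- confusion(truth, rep("virulent", 20))
  expect_equal(all_vir$TP, 10); expect_equal(all_vir$FP, 10)
  expect_equal(all_vir$TN, 0); expect_equal(all_vir$FN, 0)

  set.seed(14)
  truth2 <- sample(c("virulent", "temperate"), 60, replace = TRUE)
  pred2 <- sample(c("virulent", "temperate", "uncertain"), 60, replace = TRUE)
  cm2 <- confusion(truth2, pred2)
  hand <- c(TP = 0, FP = 0, TN = 0, FN = 0, U = 0)
  for (i in 1:60) {
    if (pred2[i] == "uncertain") hand["U"] <- hand["U"] + 1
    else if (truth2[i] == "virulent" && pred2[i] == "virulent") hand["TP"] <- hand["TP"] + 1
    else if (truth2[i] == "temperate" && pred2[i] == "virulent") hand["FP"] <- hand["FP"] + 1
    else if (truth2[i] == "temperate" && pred2[i] == "temperate") hand["TN"] <- hand["TN"] + 1
    else hand["FN"] <- hand["FN"] + 1
  }
  expect_equal(c(cm2$TP, cm2$FP, cm2$TN, cm2$FN, cm2$n_uncertain_excluded),
               unname(hand))
  expect_error(confusion(truth, rep("uncertain", 20)), "uncertain")
})

test_that("Sn/Sp/Acc follow the printed formulas", {
  m <- metrics(list(TP = 8, FN = 2, TN = 6, FP = 4))
  expect_equal(unname(m), c(0.8, 0.6, 0.7))
  expect_equal(unname(metrics(list(TP = 5, FN = 0, TN = 7, FP = 0))),
               c(1, 1, 1))
  # algebraic identity: Acc = (Sn*(TP+FN) + Sp*(TN+FP)) / total
  set.seed(4)
  for (i in 1:10) {
    ct <- as.list(stats::setNames(sample(1:30, 4), c("TP", "FP", "TN", "FN")))
    m <- metrics(ct)
    tot <- ct$TP + ct$FP + ct$TN + ct$FN
    expect_equal(m[["Acc"]],
                 (m[["Sn"]] * (ct$TP + ct$FN) + m[["Sp"]] * (ct$TN + ct$FP)) / tot)
  }
  expect_warning(m0 <- metrics(list(TP = 0, FN = 0, TN = 3, FP = 2)), "Sn")
  expect_true(is.na(m0[["Sn"]]))
})

test_that("AUC equals pairwise concordance and is rank-invariant", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(roc_auc(rep(0.5, 8), rep(c(1, 0), 4)), 0.5)
  sc <- c(0.7, 0.3, 0.6, 0.4); tr <- c(1, 0, 0, 1)
  expect_equal(roc_auc(sc, tr), oracle_auc(sc, tr))
  set.seed(10)
  for (i in 1:10) {
    sc <- round(runif(12), 1)            # induce ties
    tr <- sample(c(0, 1), 12, replace = TRUE)
    if (length(unique(tr)) < 2) next
    expect_equal(roc_auc(sc, tr), oracle_auc(sc, tr))
    expect_equal(roc_auc(qlogis(pmin(pmax(sc, .01), .99)), tr),
                 roc_auc(sc, tr))        # strictly monotone transform
  }
  expect_equal(roc_auc(c(0.2, 0.9), c("temperate", "virulent")), 1)
  expect_error(roc_auc(c(0.1, 0.2), c(1, 1)), "both classes")
})

test_that("cross-validation produces per-fold rows and aggregate summaries", {
  sb <- synthetic_benchmark(n_per_class = 6, genome_length = 3000, seed = 71)
  plan <- make_cv_folds(sb$labels, n_folds = 2, seed = 71)
  rep <- run_cross_validation(sb$genomes, sb$labels, plan, groups = "A",
                              n_train = 240, n_test = 80,
                              spec = train_spec(max_epochs = 2, patience = 2,
                                                seed = 5),
                              config_args = list(F = 8, R = 8), seed = 7)
  expect_s3_class(rep, "cv_report")
  expect_equal(nrow(rep$results), 2)
  expect_equal(rep$results$group, c("A", "A"))
  expect_equal(rep$results$n_test, c(80, 80))
  expect_equal(nrow(rep$summary), 1)
  expect_equal(rep$summary$Acc_mean, mean(rep$results$Acc))
  expect_equal(rep$summary$Acc_sd, sd(rep$results$Acc))
  expect_true(all(rep$results$Acc >= 0 & rep$results$Acc <= 1))
})

test_that("ablation trains every requested variant on the same benchmark", {
  sb <- synthetic_benchmark(n_per_class = 4, genome_length = 3000, seed = 81)
  plan <- make_cv_folds(sb$labels, n_folds = 2, seed = 81)
  bench <- build_benchmark(sb$genomes, sb$labels, plan, 1, "A",
                           n_train = 160, n_test = 60, seed = 3)
  tab <- run_ablation(bench, variants = c("full", "kmer4", "no_bn"),
                      config = network_config(L = 400, F = 8, R = 8),
                      spec = train_spec(max_epochs = 2, patience = 2, seed = 9))
  expect_equal(tab$variant, c("full", "kmer4", "no_bn"))
  expect_equal(nrow(tab), 3)
  expect_true(all(is.finite(tab$Acc)))
  expect_true(all(tab$Acc >= 0 & tab$Acc <= 1))
  expect_error(run_ablation(bench, variants = "dropout_everywhere",
                            config = network_config(L = 400)),
               "variants")
})
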
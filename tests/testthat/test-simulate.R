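test_that("length-group assignment covers ranges, boundaries and directives", {
  expect_equal(assign_length_group(250), "A")
  expect_equal(assign_length_group(1500), "D")
  expect_equal(assign_length_group(c(399, 400)), c("A", "B"))
  expect_equal(assign_length_group(c(799, 800, 1199, 1200)),
               c("B", "C", "C", "D"))
  expect_equal(assign_length_group(99), "short")
  expect_equal(assign_length_group(1800), "D")
  expect_equal(assign_length_group(1801), "split")
  expect_error(assign_length_group(0), ">= 1")
})

test_that("extract_fragments yields in-range exact substrings, deterministically", {
  withr::with_seed(2, {
    genome <- rand_seq(10000)
  })
  fr <- extract_fragments(genome, "virulent", "D", 50, seed = 9,
                          genome_id = "g1")
  expect_equal(nrow(fr), 50L)
  expect_true(all(fr$length >= 1200 & fr$length <= 1800))
  expect_true(all(fr$start >= 0 & fr$start + fr$length <= 10000))
  expect_identical(fr$bases,
                   substring(genome, fr$start + 1, fr$start + fr$length))
  fr2 <- extract_fragments(genome, "virulent", "D", 50, seed = 9,
                           genome_id = "g1")
  expect_identical(fr, fr2)

  expect_equal(nrow(extract_fragments(genome, "temperate", "A", 0)), 0L)
  expect_warning(out <- extract_fragments(rand_seq(500), "virulent", "D", 5),
                 "shorter")
  expect_equal(nrow(out), 0L)
})

test_that("fragment start positions are uniform over valid offsets", {
  withr::with_seed(4, genome <- rand_seq(100000))
  fr <- extract_fragments(genome, "virulent", "D", 10000, seed = 21)
  # rescale each start by its own valid range; the result should be ~U(0,1)
  u <- (fr$start + 0.5) / (100000 - fr$length + 1)
  ks <- suppressWarnings(stats::ks.test(u, "punif"))
  expect_gt(ks$p.value, 0.01)
  # lengths: uniform over [1200, 1800], mean near the midpoint within 2 SE
  se <- sqrt(((1800 - 1200 + 1)^2 - 1) / 12 / nrow(fr))
  expect_lt(abs(mean(fr$length) - 1500), 2 * se)
})

test_that("cross-validation folds stratify by lifestyle and partition genomes", {
  labels <- data.frame(genome_id = paste0("g", 1:10),
                       lifestyle = rep(c("virulent", "temperate"), each = 5),
                       dataset = "curated", stringsAsFactors = FALSE)
  plan <- make_cv_folds(labels, n_folds = 5, seed = 1)
  expect_equal(sort(names(plan$assignments)), sort(labels$genome_id))
  for (f in 1:5) {
    ids <- names(plan$assignments)[plan$assignments == f]
    cls <- labels$lifestyle[match(ids, labels$genome_id)]
    expect_equal(sort(cls), c("temperate", "virulent"))
  }
  expect_error(make_cv_folds(labels, n_folds = 6), "virulent")

  # auto genomes go to always_train
  labels2 <- rbind(labels, data.frame(genome_id = "auto1",
                                      lifestyle = "virulent",
                                      dataset = "auto"))
  plan2 <- make_cv_folds(labels2, n_folds = 5, seed = 1)
  expect_equal(plan2$always_train, "auto1")
  expect_false("auto1" %in% names(plan2$assignments))
})

test_that("build_benchmark is leakage-free, balanced and deterministic", {
  sb <- synthetic_benchmark(n_per_class = 6, genome_length = 4000, seed = 31)
  plan <- make_cv_folds(sb$labels, n_folds = 3, seed = 31)
  for (fold in 1:3) {
    bench <- build_benchmark(sb$genomes, sb$labels, plan, fold, "A",
                             n_train = 300, n_test = 101, seed = 5)
    expect_length(intersect(unique(bench$train$genome_id),
                            unique(bench$test$genome_id)), 0)
    expect_equal(nrow(bench$train), 300L)
    expect_equal(nrow(bench$test), 101L)
    tab <- table(bench$train$lifestyle)
    expect_lte(abs(tab[["virulent"]] - tab[["temperate"]]), 1)
    expect_true(all(bench$train$length >= 100 & bench$train$length <= 399))
    # test genomes are exactly the fold's curated genomes
    expect_true(all(unique(bench$test$genome_id) %in%
                      names(plan$assignments)[plan$assignments == fold]))
  }
  b1 <- build_benchmark(sb$genomes, sb$labels, plan, 1, "A", 200, 50, seed = 8)
  b2 <- build_benchmark(sb$genomes, sb$labels, plan, 1, "A", 200, 50, seed = 8)
  expect_identical(b1, b2)
})

test_that("Markov genome generator matches its chain's stationary composition", {
  unif <- synthetic_class_model(matrix(0.25, 4, 4), genome_length = 100000,
                                label = "virulent")
  g <- generate_synthetic_genomes(unif, 1, seed = 3)
  freqs <- table(factor(strsplit(g$bases, "")[[1]], c("A", "C", "G", "T")))
  expect_true(all(abs(freqs / 100000 - 0.25) < 0.01))

  g2 <- generate_synthetic_genomes(unif, 1, seed = 3)
  expect_identical(g, g2)

  gc_biased <- matrix(rep(c(0.05, 0.45, 0.45, 0.05), each = 4), 4, 4)
  m <- synthetic_class_model(gc_biased, genome_length = 50000,
                             label = "temperate")
  gg <- generate_synthetic_genomes(m, 1, seed = 5)
  gc_obs <- mean(strsplit(gg$bases, "")[[1]] %in% c("G", "C"))
  pi_st <- oracle_stationary(gc_biased)
  gc_exp <- pi_st[2] + pi_st[3]
  expect_gt(gc_obs, 0.5)
  expect_lt(abs(gc_obs - gc_exp), 0.02)

  expect_error(synthetic_class_model(matrix(0.3, 4, 4), label = "virulent"),
               "sum to 1")
})

test_that("benchmark class models implement the stated 85:15 GC mixing", {
  models <- benchmark_class_models()
  vir <- models$virulent$transition
  tem <- models$temperate$transition
  gc_row <- c(0.05, 0.45, 0.45, 0.05)
  for (i in 1:4)
    expect_equal(unname(tem[i, ]), unname(0.85 * vir[i, ] + 0.15 * gc_row))
  expect_equal(unname(rowSums(vir)), rep(1, 4))
  expect_equal(unname(rowSums(tem)), rep(1, 4))
  # the temperate stationary GC content exceeds the virulent one
  expect_gt(sum(oracle_stationary(tem)[2:3]), sum(oracle_stationary(vir)[2:3]))
})
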
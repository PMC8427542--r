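test_that("long sequences split into 1800 bp pieces plus remainder", {
  s4000 <- rand_seq(4000)
  sp <- split_long_sequence(s4000)
  expect_equal(sp$length, c(1800L, 1800L, 400L))
  expect_equal(paste0(sp$bases, collapse = ""), s4000)

  expect_equal(split_long_sequence(rand_seq(3600))$length, c(1800L, 1800L))
  sp2 <- split_long_sequence(rand_seq(1801))
  expect_equal(sp2$length, c(1800L, 1L))
  expect_error(split_long_sequence(rand_seq(1800)), "longer than 1800")
})

test_that("score combination is the length-weighted mean", {
  expect_equal(combine_scores(c(1800, 1800, 400), c(0.8, 0.8, 0.2)), 0.74)
  expect_equal(combine_scores(c(5, 100, 3), rep(0.42, 3)), 0.42)
  expect_equal(combine_scores(700, 0.9), 0.9)
  expect_error(combine_scores(numeric(0), numeric(0)), "no piece")
  expect_error(combine_scores(c(10, 0), c(0.5, 0.5)), "positive")
  set.seed(2)
  for (i in 1:20) {
    n <- sample(1:5, 1)
    lens <- sample(1:1800, n); sc <- runif(n)
    comb <- combine_scores(lens, sc)
    expect_gte(comb, min(sc)); expect_lte(comb, max(sc))
  }
})

test_that("classification respects the uncertain band and its tie-break", {
  expect_equal(classify(0.9, cutoff_policy(0)), "virulent")
  expect_equal(classify(0.6, cutoff_policy(0.5)), "uncertain")
  expect_equal(classify(0.2, cutoff_policy(0.5)), "temperate")
  expect_equal(classify(0.5, cutoff_policy(0)), "uncertain")
  expect_equal(classify(0.5, cutoff_policy(0.5)), "uncertain")
  expect_equal(classify(c(0.75, 0.25), cutoff_policy(0.5)),
               c("uncertain", "uncertain"))  # band is open
  expect_error(cutoff_policy(1), "t must be")

  # monotonicity in score; monotonicity of uncertainty in t
  set.seed(6)
  sc <- sort(runif(50))
  lab <- classify(sc, cutoff_policy(0.3))
  ord <- match(lab, c("temperate", "uncertain", "virulent"))
  expect_true(all(diff(ord) >= 0))
  n_unc <- vapply(c(0, 0.2, 0.5, 0.8),
                  function(t) sum(classify(sc, cutoff_policy(t)) == "uncertain"),
                  numeric(1))
  expect_true(all(diff(n_unc) >= 0))
})

test_that("routing sends each length to its group model and combines pieces", {
  models <- tiny_model_set(seed = 44)
  withr::with_seed(9, {
    s250 <- rand_seq(250); s1500 <- rand_seq(1500)
    s50 <- rand_seq(50); s5000 <- rand_seq(5000)
  })
  expect_equal(route_and_score(s250, models), predict(models$A, s250))
  expect_equal(route_and_score(s1500, models), predict(models$D, s1500))
  expect_equal(route_and_score(s50, models), predict(models$A, s50))

  sp <- split_long_sequence(s5000)
  expect_equal(sp$length, c(1800L, 1800L, 1400L))
  piece_scores <- predict(models$D, sp$bases)
  expect_equal(route_and_score(s5000, models),
               combine_scores(sp$length, piece_scores))

  # a remainder below 100 bp falls to the group A model
  s1850 <- rand_seq(1850)
  sp2 <- split_long_sequence(s1850)
  manual <- combine_scores(sp2$length,
                           c(predict(models$D, sp2$bases[1]),
                             predict(models$A, sp2$bases[2])))
  expect_equal(route_and_score(s1850, models), manual)

  # inference determinism: a duplicated sequence scores identically
  out <- route_and_score(c(s250, s1500, s250), models)
  expect_identical(out[1], out[3])

  expect_error(route_and_score(s250, models[c("A", "B")]), "group")
})

test_that("predict_file writes one ordered row per record and a summary", {
  models <- tiny_model_set(seed = 3)
  withr::with_seed(31, {
    fa <- write_tmp_fasta(c(">q1", rand_seq(150), ">q2", rand_seq(2500),
                            ">q3", rand_seq(950)))
  })
  out <- tempfile(fileext = ".tsv")
  res <- predict_file(fa, models, cutoff_policy(0.2), out)
  rep <- read_prediction_report(out)
  expect_equal(rep$id, c("q1", "q2", "q3"))
  expect_equal(rep$length, c(150L, 2500L, 950L))
  expect_equal(res$n, 3)
  expect_equal(res$n_virulent + res$n_temperate + res$n_uncertain, res$n)
  expect_true(all(rep$label %in% c("virulent", "temperate", "uncertain")))

  empty_fa <- write_tmp_fasta(character(0))
  out2 <- tempfile(fileext = ".tsv")
  expect_warning(res2 <- predict_file(empty_fa, models, cutoff_policy(0), out2))
  expect_equal(res2$n, 0)
  expect_equal(readLines(out2), "id\tlength\tscore\tlabel")
})
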
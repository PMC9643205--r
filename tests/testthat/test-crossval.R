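test_that("fold splits have exact sizes and are reproducible", {
  folds <- split_folds(100L, 5L, seed = 61L)
  expect_equal(length(folds), 5L)
  for (f in folds) {
    expect_equal(length(f$test_indices), 20L)
    expect_equal(length(f$learn_indices), 80L)
    expect_equal(sort(c(f$test_indices, f$learn_indices)), 1:100)
  }
  expect_identical(split_folds(100L, 5L, seed = 61L), folds)
  expect_false(identical(split_folds(100L, 5L, seed = 62L), folds))

  # the published protocol sizes: one fifth of 6060 columns
  f6060 <- split_folds(6060L, 5L, seed = 63L)
  expect_true(all(vapply(f6060, function(f) length(f$test_indices),
                         0L) == 1212L))

  # independent resampling: replicates overlap in general
  ov <- length(intersect(folds[[1L]]$test_indices, folds[[2L]]$test_indices))
  expect_gt(ov, 0L)
  # strict partition mode: disjoint and exhaustive
  part <- split_folds(101L, 5L, seed = 64L, partition = TRUE)
  all_test <- unlist(lapply(part, `[[`, "test_indices"))
  expect_equal(sort(all_test), 1:101)
  expect_error(split_folds(100L, fraction = 1.2), "fraction")
  expect_error(split_folds(3L, 5L), "n_sites")
})

test_that("many random splits keep exact sizes", {
  set.seed(65)
  for (i in 1:200) {
    n <- sample(10:5000, 1L)
    f <- split_folds(n, 1L, seed = sample.int(1e6, 1L))[[1L]]
    expect_equal(length(f$test_indices), round(n / 5))
    expect_equal(length(f$test_indices) + length(f$learn_indices), n)
  }
})

test_that("the cv-score is the log of the posterior-mean site likelihood", {
  aln <- aa_alignment(c(A = "A", B = "A"))
  # one site, K = 2, p-values {0.2, 0.4}: score = ln 0.3
  s <- cv_score(aln, fake_fit(c(0.2, 0.4)))
  expect_equal(s$score, log(0.3), tolerance = 1e-12)
  expect_equal(s$K, 2L)
  # identical draws: independent of K
  expect_equal(cv_score(aln, fake_fit(rep(0.2, 7L)))$score, log(0.2),
               tolerance = 1e-12)
  expect_equal(cv_score(aln, fake_fit(0.2))$score, log(0.2),
               tolerance = 1e-12)
})

test_that("with K = 1 the cv-score is the test-set log-likelihood", {
  set.seed(66)
  sim <- make_benchmark_suite(3L, which = "smoke")$smoke
  fold <- split_folds(50L, 1L, seed = 5L)[[1L]]
  fit <- run_chain(sim$alignment[fold$learn_indices], sim$tree,
                   model_spec("poisson", "single", gamma = TRUE),
                   cfg = chain_config(n_cycles = 31L, burn_in = 30L,
                                      seed = 7L))
  expect_equal(fit$K, 1L)
  test_aln <- sim$alignment[fold$test_indices]
  s <- cv_score(test_aln, fit)
  d <- fit$draws[[1L]]
  model <- mixcv:::draw_to_model(fit, d)
  expect_equal(s$score,
               log_likelihood(test_aln, fit$tree, model, bl = d$bl),
               tolerance = 1e-10)
})

test_that("relative score tables aggregate differences correctly", {
  df <- expand.grid(model = c("ref", "better"), replicate = 1:5,
                    stringsAsFactors = FALSE)
  base <- c(-100, -120, -90, -110, -105)
  df$score <- ifelse(df$model == "ref", base[df$replicate],
                     base[df$replicate] + df$replicate)
  rep1 <- relative_score_table(df, "ref")
  tab <- rep1$table
  expect_equal(tab$mean[tab$model == "ref"], 0)
  expect_equal(tab$sd[tab$model == "ref"], 0)
  expect_equal(tab$mean[tab$model == "better"], 3)
  expect_equal(tab$sd[tab$model == "better"], sd(1:5), tolerance = 1e-12)
  expect_equal(sum(tab$best), 5L)

  # shifting every model by a per-replicate constant changes nothing
  df2 <- df
  df2$score <- df2$score + 17 * df2$replicate
  expect_equal(relative_score_table(df2, "ref")$table$mean, tab$mean)

  expect_error(relative_score_table(df[-1L, ], "ref"), "missing")
  expect_error(relative_score_table(df, "nope"), "reference")
})

test_that("best-model tallies count wins and split exact ties", {
  df <- data.frame(model = rep(c("A", "B"), 5L),
                   replicate = rep(1:5, each = 2L),
                   score = c(1, 0, 0, 1, 1, 0, 0, 1, 1, 0))
  expect_equal(best_model_tally(df), c(A = 3L, B = 2L))
  df$score[1:2] <- c(2, 2)
  expect_message(t2 <- best_model_tally(df), "tie")
  expect_equal(t2, c(A = 3L, B = 3L))
  expect_equal(sum(best_model_tally(df) > 0), 2L)
})

test_that("run_experiment orchestrates, reuses fits, and is deterministic", {
  sim <- make_benchmark_suite(3L, which = "smoke")$smoke
  models <- list(model_spec("poisson", "single", gamma = FALSE),
                 model_spec("poisson", "single", gamma = TRUE))
  dir1 <- withr::local_tempdir()
  cfg <- experiment_config(models, alignment = sim$alignment,
                           tree = sim$tree,
                           chain = chain_config(n_cycles = 40L,
                                                burn_in = 10L),
                           n_replicates = 2L, reference = "F81",
                           out_dir = dir1, seed = 31L)
  rep1 <- run_experiment(cfg)
  expect_s3_class(rep1, "cv_report")
  expect_equal(nrow(rep1$table), 2L)
  expect_equal(sum(rep1$table$best), 2L)
  # manifest completeness
  manifest <- readLines(file.path(dir1, "manifest.txt"))
  expect_true(all(file.exists(manifest)))
  expect_equal(sum(grepl("^fit_", basename(manifest))), 4L)

  # a second run in the same directory reuses the stored fits
  t0 <- Sys.time()
  rep2 <- run_experiment(cfg)
  expect_lt(as.numeric(Sys.time() - t0, units = "secs"), 10)
  expect_equal(rep2$scores, rep1$scores)

  # same master seed in a fresh directory reproduces the report exactly
  dir2 <- withr::local_tempdir()
  cfg2 <- cfg
  cfg2$out_dir <- dir2
  rep3 <- run_experiment(cfg2)
  expect_equal(rep3$scores, rep1$scores)

  expect_error(experiment_config(models, alignment = sim$alignment,
                                 tree = sim$tree, reference = "GTR+G",
                                 out_dir = dir1),
               "config error")
  expect_error(experiment_config(list(), out_dir = dir1), "config error")
})

test_that("posterior prediction scores new columns site by site", {
  set.seed(67)
  sim <- make_benchmark_suite(3L, which = "smoke")$smoke
  fit <- run_chain(sim$alignment[1:40], sim$tree,
                   model_spec("poisson", "single", gamma = FALSE),
                   cfg = chain_config(n_cycles = 40L, burn_in = 20L,
                                      seed = 8L))
  newdata <- sim$alignment[41:50]
  ll <- predict(fit, newdata)
  expect_equal(length(ll), 10L)
  expect_true(all(ll < 0))
  expect_equal(sum(ll), cv_score(newdata, fit)$score, tolerance = 1e-12)
})
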
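fake_manifest <- function(n_groups, k_sources = 10) {
  src <- sprintf("p%02d", rep_len(seq_len(k_sources), n_groups))
  off <- as.integer(ave(seq_len(n_groups), src, FUN = seq_along)) - 1L
  data.frame(sample_id = c(paste0(src, "_", off, "_d"),
                           paste0(src, "_", off, "_r")),
             source_id = rep(src, 2),
             window_offset = rep(off, 2),
             orientation = rep(c("direct", "reversed"), each = n_groups),
             stringsAsFactors = FALSE)
}

test_that("folds are balanced and keep direct/reversed pairs together", {
  man <- fake_manifest(100)
  folds <- make_folds(man, k = 5, seed = 1)
  expect_equal(as.integer(table(folds)), rep(40L, 5))  # 20 groups x 2 samples
  key <- paste(man$source_id, man$window_offset)
  for (g in unique(key))
    expect_length(unique(folds[key == g]), 1L)
  # seeding: same seed same folds, different seed different folds
  expect_identical(folds, make_folds(man, k = 5, seed = 1))
  expect_false(identical(folds, make_folds(man, k = 5, seed = 2)))
  # decoys of one parent are allowed to span folds (the stated leakage)
  expect_gt(length(unique(folds[man$source_id == "p01"])), 1L)
})

test_that("strict mode keeps whole parents in one fold", {
  man <- fake_manifest(100)
  folds <- make_folds(man, k = 5, seed = 3, strict = TRUE)
  for (s in unique(man$source_id))
    expect_length(unique(folds[man$source_id == s]), 1L)
})

test_that("unpaired reversed samples are rejected", {
  man <- fake_manifest(10)
  man <- man[-1, ]                       # drop one direct sample
  expect_error(make_folds(man, k = 2, seed = 1), "without a direct")
})

test_that("baseline predictor and its toy MAPE closed form", {
  train <- rbind(rep(1, 10), rep(3, 10))
  pred <- baseline_predict(train, 2)
  expect_equal(pred, matrix(2, 2, 10))
  # on its own training samples: 100 * (1 + 1/3) / 2
  expect_equal(mape(train, pred), 100 * (1 + 1 / 3) / 2)
  expect_error(baseline_predict(train[0, , drop = FALSE], 1), "empty")
})

test_that("evaluation_report separates per-eigenvalue and overall scores", {
  true <- matrix(c(1, 2, 2, 4), 2)
  pred <- matrix(c(1.1, 2, 2, 5), 2)
  rep_ <- evaluation_report(true, pred, context = "evaluation")
  expect_equal(rep_$per_eigenvalue, c(5, 12.5))
  expect_equal(rep_$overall, mean(c(mean(c(10, 0)), mean(c(0, 25)))))
  expect_equal(rep_$n_samples, 2L)
})

test_that("the CV harness returns exactly zero MAPE for the exact oracle", {
  set.seed(10)
  n_groups <- 12
  man <- fake_manifest(n_groups, k_sources = 4)
  n <- nrow(man)
  x <- array(runif(n * 8 * 8), c(n, 8, 8))
  y <- matrix(runif(n * 10, 0.5, 3), n)
  ds <- list(x = x, y = y, manifest = man)
  rep_ <- cross_validate(ds, k = 3, repeats = 2,
                         predictor = make_cv_oracle(y))
  expect_identical(rep_$overall_mean, 0)
  expect_identical(max(rep_$per_eigenvalue_mean), 0)
  expect_equal(rep_$n_runs, 6L)
})

test_that("failed folds are recorded and excluded", {
  man <- fake_manifest(6, k_sources = 2)
  n <- nrow(man)
  ds <- list(x = array(runif(n * 4 * 4), c(n, 4, 4)),
             y = matrix(runif(n * 2, 0.5, 1), n), manifest = man)
  flaky <- local({
    calls <- 0L
    function(tx, ty, ex) {
      calls <<- calls + 1L
      if (calls == 1L) stop("boom")
      matrix(1, dim(ex)[1], ncol(ty))
    }
  })
  expect_warning(rep_ <- cross_validate(ds, k = 2, repeats = 1,
                                        predictor = flaky),
                 "boom")
  expect_equal(rep_$n_failures, 1L)
  expect_equal(rep_$n_runs, 1L)
})

test_that("a reduced CV with the real network completes and reports", {
  ds <- fx_eval_dataset()          # 30 direct samples, 100x100
  # pair manifest requirement: no reversed rows present, so pairing is
  # trivially satisfied (each group is a singleton)
  sub <- list(x = ds$x[1:20, , , drop = FALSE], y = ds$y[1:20, ],
              manifest = ds$manifest[1:20, ])
  rep_ <- cross_validate(sub, surrogate_config(seed = 1), k = 2,
                         repeats = 1, epochs = 2, batch_size = 5)
  expect_length(rep_$per_eigenvalue_mean, 10L)
  expect_true(all(is.finite(rep_$per_eigenvalue_mean)))
  expect_equal(rep_$n_runs, 2L)
  path <- tempfile(fileext = ".tsv")
  write_report_tsv(rep_, path)
  tab <- read.delim(path)
  expect_equal(nrow(tab), 11L)     # 10 eigenvalues + overall
})
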
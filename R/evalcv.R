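#' Build cross-validation folds with the direct/reversed pairing constraint
#'
#' The grouping unit is a structure together with its reversed copy (same
#' `source_id` and `window_offset`, opposite orientation): the two always
#' land in the same fold, because they share the target and differ only by a
#' deterministic transformation of the input.  Groups are shuffled with the
#' seed and dealt round-robin into `k` folds, so fold sizes differ by at
#' most one group.  Decoys cut from the same parent chain may land in
#' different folds -- a known, deliberate leakage of the protocol -- unless
#' `strict = TRUE`, which groups by parent `source_id` instead.
#'
#' @param manifest data.frame with columns `source_id`, `window_offset`,
#'   `orientation` (one row per sample, as produced by [build_dataset()]).
#' @param k number of folds.
#' @param seed integer seed for the shuffle.
#' @param strict group whole parent chains instead of single decoys?
#' @return integer vector of fold indices (1..k), one per manifest row.
#' @export
make_folds <- function(manifest, k = 5L, seed = 0L, strict = FALSE) {
  stopifnot(k >= 2L, nrow(manifest) >= k)
  key <- if (strict) manifest$source_id
         else paste(manifest$source_id, manifest$window_offset, sep = "|")
  rev_rows <- manifest$orientation == "reversed"
  if (!strict) {
    unpaired <- setdiff(unique(key[rev_rows]), unique(key[!rev_rows]))
    if (length(unpaired))
      stop("reversed sample(s) without a direct counterpart: ",
           paste(utils::head(unpaired, 3L), collapse = ", "))
  }
  groups <- unique(key)
  perm <- with_seed(seed, sample.int(length(groups)))
  fold_of_group <- integer(length(groups))
  fold_of_group[perm] <- rep_len(seq_len(k), length(groups))
  folds <- fold_of_group[match(key, groups)]
  stopifnot(!anyNA(folds))
  folds
}

#' Non-informative baseline predictor
#'
#' Predicts, for every test sample, the elementwise mean of the training
#' targets: the reference any learned model has to beat.
#'
#' @param train_targets matrix (samples x modes) of training eigenvalues.
#' @param n_test number of test samples.
#' @return matrix (n_test x modes) of constant predictions.
#' @export
baseline_predict <- function(train_targets, n_test) {
  train_targets <- as.matrix(train_targets)
  if (!nrow(train_targets)) stop("empty training targets")
  matrix(colMeans(train_targets), nrow = n_test,
         ncol = ncol(train_targets), byrow = TRUE)
}

#' Summarise predictions against true spectra
#'
#' @param true,predicted matrices (samples x modes).
#' @param context one of `"cross_validation"`, `"evaluation"`, `"baseline"`.
#' @return an `evaluation_report`: per-eigenvalue MAPE (mean over samples of
#'   the i-th relative error), overall MAPE (mean over samples of per-sample
#'   means), and sample count.
#' @export
evaluation_report <- function(true, predicted,
                              context = c("evaluation", "cross_validation",
                                          "baseline")) {
  context <- match.arg(context)
  true <- as.matrix(true); predicted <- as.matrix(predicted)
  stopifnot(identical(dim(true), dim(predicted)))
  rel <- 100 * abs(predicted - true) / abs(true)
  structure(list(per_eigenvalue = colMeans(rel),
                 overall = mean(rowMeans(rel)),
                 context = context,
                 n_samples = nrow(true)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %s over %d samples: overall MAPE %.2f%%\n",
              x$context, x$n_samples, x$overall))
  cat("per-eigenvalue:",
      paste(sprintf("%.1f", x$per_eigenvalue), collapse = " "), "\n")
  invisible(x)
}

#' Repeated k-fold cross-validation of the surrogate
#'
#' For each repeat (one network seed per repeat, the same seeds used for
#' full-dataset training) and each fold: train on the other k-1 folds, score
#' MAPE on the held-out fold; report per-eigenvalue and overall MAPE with
#' mean and standard deviation across the `repeats * k` runs.  A functional
#' `predictor` can replace the network (e.g. the exact spectral oracle, or
#' the non-informative baseline) to validate the harness itself.
#'
#' @param dataset list with `x`, `y`, `manifest` (see [build_dataset()]).
#' @param config a [surrogate_config()]; its seed is replaced by the repeat
#'   seed.
#' @param k folds per repeat.
#' @param repeats number of repeats.
#' @param seeds one integer per repeat (default `0:(repeats-1)`).
#' @param epochs,batch_size training-schedule overrides for reduced runs.
#' @param predictor optional `function(train_x, train_y, test_x)` returning
#'   a prediction matrix, bypassing the network; a function with a fourth
#'   argument also receives the test-row indices (so an exact oracle can
#'   look the true spectra up).
#' @param strict forward to [make_folds()].
#' @param verbose print progress?
#' @return a `cv_report`: aggregated per-eigenvalue and overall MAPE
#'   (mean and sd across runs) plus the individual run reports.
#' @export
cross_validate <- function(dataset, config = surrogate_config(), k = 5L,
                           repeats = 10L, seeds = NULL, epochs = NULL,
                           batch_size = NULL, predictor = NULL,
                           strict = FALSE, verbose = FALSE) {
  if (is.null(seeds)) seeds <- seq_len(repeats) - 1L
  stopifnot(length(seeds) == repeats)
  x <- dataset$x; y <- dataset$y; manifest <- dataset$manifest
  runs <- list(); failures <- 0L
  for (r in seq_len(repeats)) {
    folds <- make_folds(manifest, k = k, seed = seeds[r], strict = strict)
    for (f in seq_len(k)) {
      test_idx <- which(folds == f)
      train_idx <- which(folds != f)
      res <- tryCatch({
        pred <- if (!is.null(predictor)) {
          if (length(formals(predictor)) >= 4L)
            predictor(x[train_idx, , , drop = FALSE],
                      y[train_idx, , drop = FALSE],
                      x[test_idx, , , drop = FALSE], test_idx)
          else
            predictor(x[train_idx, , , drop = FALSE],
                      y[train_idx, , drop = FALSE],
                      x[test_idx, , , drop = FALSE])
        } else {
          cfg <- config; cfg$seed <- as.integer(seeds[r])
          model <- build_surrogate(cfg)
          model <- train_surrogate(model, x[train_idx, , , drop = FALSE],
                                   y[train_idx, , drop = FALSE],
                                   epochs = epochs, batch_size = batch_size)
          predict(model, x[test_idx, , , drop = FALSE])
        }
        evaluation_report(y[test_idx, , drop = FALSE], pred,
                          context = "cross_validation")
      }, error = function(e) e)
      if (inherits(res, "error")) {
        warning("repeat ", r, " fold ", f, " failed: ",
                conditionMessage(res))
        failures <- failures + 1L
      } else {
        runs[[length(runs) + 1L]] <- res
      }
      if (verbose && !inherits(res, "error"))
        message(sprintf("repeat %d fold %d: MAPE %.2f%%", r, f,
                        res$overall))
    }
  }
  if (!length(runs)) stop("all cross-validation runs failed")
  per <- do.call(rbind, lapply(runs, `[[`, "per_eigenvalue"))
  overall <- vapply(runs, `[[`, numeric(1), "overall")
  structure(list(per_eigenvalue_mean = colMeans(per),
                 per_eigenvalue_sd = apply(per, 2L, stats::sd),
                 overall_mean = mean(overall),
                 overall_sd = stats::sd(overall),
                 n_runs = length(runs), n_failures = failures,
                 k = k, repeats = repeats, seeds = seeds,
                 runs = runs),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf(paste0("<cv_report> %dx%d cross-validation (%d runs, %d",
                     " failed): overall MAPE %.2f%% (sd %.2f)\n"),
              x$repeats, x$k, x$n_runs, x$n_failures,
              x$overall_mean, if (is.na(x$overall_sd)) 0 else x$overall_sd))
  invisible(x)
}

#' Write an evaluation or CV report as TSV
#'
#' One row per (context, eigenvalue index), plus an `overall` row.
#'
#' @param report an `evaluation_report` or `cv_report`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_report_tsv <- function(report, path) {
  if (inherits(report, "cv_report")) {
    tab <- data.frame(context = "cross_validation",
                      eigenvalue = c(seq_along(report$per_eigenvalue_mean),
                                     NA),
                      mape = c(report$per_eigenvalue_mean,
                               report$overall_mean),
                      sd = c(report$per_eigenvalue_sd, report$overall_sd))
  } else {
    tab <- data.frame(context = report$context,
                      eigenvalue = c(seq_along(report$per_eigenvalue), NA),
                      mape = c(report$per_eigenvalue, report$overall),
                      sd = NA_real_)
  }
  tab$eigenvalue[is.na(tab$eigenvalue)] <- "overall"
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
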
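#' Pipeline run configuration
#'
#' One structured configuration object drives the end-to-end recipes: paths,
#' elastic-network parameters, surrogate architecture, dataset generation
#' settings, cross-validation plan and pruning scheme.  Every stochastic
#' stage derives its seed from `seed` plus the repeat index, so a run is
#' reproducible from the config alone.
#'
#' @param out_dir directory for datasets, models and reports.
#' @param n_parents number of synthetic parent chains for `build_dataset`.
#' @param parent_lengths integer vector of parent chain lengths to cycle
#'   through (the window-sliding decoy construction turns a chain of length
#'   `window + N` into `N + 1` decoys).
#' @param compactness_range range the parents' compactness is drawn from.
#'   The default 0.5--0.9 yields gyration radii of roughly 10--13 Angstrom
#'   for 100-residue chains -- the globularity range of real single-domain
#'   proteins -- and guarantees mechanically rigid structures (exactly 6
#'   zero modes); below ~0.4 the walks become floppy, with near-zero
#'   eigenvalues real proteins do not show.
#' @param gly_fraction glycine fraction of synthetic sequences.
#' @param window decoy window = surrogate input size.
#' @param params an [enm_params()].
#' @param surrogate a [surrogate_config()].
#' @param epochs,batch_size training-schedule overrides (NULL = config
#'   defaults).
#' @param cv_k,cv_repeats cross-validation plan.
#' @param pruning a [pruning_scheme()].
#' @param seed master seed.
#' @return an object of class `run_config`.
#' @export
run_config <- function(out_dir = tempfile("enmspec_run_"),
                       n_parents = 20L,
                       parent_lengths = 101:110,
                       compactness_range = c(0.5, 0.9),
                       gly_fraction = 0.08,
                       window = 100L,
                       params = enm_params(),
                       surrogate = surrogate_config(input_size = window),
                       epochs = NULL, batch_size = NULL,
                       cv_k = 5L, cv_repeats = 10L,
                       pruning = pruning_scheme("random"),
                       seed = 1L) {
  structure(list(out_dir = out_dir, n_parents = as.integer(n_parents),
                 parent_lengths = as.integer(parent_lengths),
                 compactness_range = compactness_range,
                 gly_fraction = gly_fraction, window = as.integer(window),
                 params = params, surrogate = surrogate,
                 epochs = epochs, batch_size = batch_size,
                 cv_k = as.integer(cv_k),
                 cv_repeats = as.integer(cv_repeats),
                 pruning = pruning, seed = as.integer(seed)),
            class = "run_config")
}

config_hash <- function(config) {
  # order-stable digest of the config for dataset caching
  s <- paste(deparse(config[setdiff(names(config), "out_dir")]),
             collapse = "")
  sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 997 + 1)) %% 2147483647
}

#' Generate the synthetic decoy training chains of a run
#'
#' @param config a [run_config()].
#' @return list of parent [chain_structure()]s.
#' @export
generate_parents <- function(config) {
  lens <- rep_len(config$parent_lengths, config$n_parents)
  lapply(seq_len(config$n_parents), function(i) {
    cmp <- with_seed(config$seed * 1000L + i,
                     stats::runif(1, config$compactness_range[1],
                                  config$compactness_range[2]))
    generate_synthetic_chain(lens[i], compactness = cmp,
                             gly_fraction = config$gly_fraction,
                             seed = config$seed * 1000L + i,
                             source_id = sprintf("parent%03d", i))
  })
}

#' Execute one end-to-end recipe
#'
#' Recipes: `build_dataset` (synthetic parents -> decoys -> reversal
#' augmentation -> descriptors + spectra on disk), `train_full` (train one
#' surrogate on the cached dataset), `cross_validate`, `baseline` (score the
#' non-informative mean predictor on the cached dataset via a held-out
#' split), and `prune_predict` (prune a dumbbell fixture and score the
#' trained model against the full-chain spectrum).  `build_dataset` is
#' cached: a re-run with an unchanged config reuses the dataset directory.
#'
#' @param config a [run_config()].
#' @param recipe recipe name.
#' @param verbose print progress?
#' @return the recipe's main artifact (dataset, model, report), invisibly;
#'   artifacts are also written under `config$out_dir`.
#' @export
run_pipeline <- function(config, recipe = c("build_dataset", "train_full",
                                            "cross_validate", "baseline",
                                            "prune_predict"),
                         verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  if (!recipe[1] %in% c("build_dataset", "train_full", "cross_validate",
                        "baseline", "prune_predict"))
    stop("unknown recipe '", recipe[1], "'; valid recipes: build_dataset, ",
         "train_full, cross_validate, baseline, prune_predict")
  recipe <- match.arg(recipe)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  data_dir <- file.path(config$out_dir, "dataset")
  hash_file <- file.path(data_dir, "config_hash.txt")

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  get_dataset <- function() {
    if (file.exists(hash_file) &&
        identical(readLines(hash_file), as.character(config_hash(config)))) {
      if (verbose) message("reusing cached dataset in ", data_dir)
      return(read_dataset(data_dir))
    }
    parents <- stage("generate_parents", generate_parents(config))
    decoys <- stage("make_decoys",
                    unlist(lapply(parents, make_decoys,
                                  window = config$window),
                           recursive = FALSE))
    ds <- stage("build_dataset",
                build_dataset(decoys, params = config$params,
                              augment_reversed = TRUE))
    write_dataset(ds, data_dir)
    writeLines(as.character(config_hash(config)), hash_file)
    ds
  }

  switch(recipe,
    build_dataset = invisible(get_dataset()),
    train_full = {
      ds <- get_dataset()
      cfg <- config$surrogate; cfg$seed <- config$seed
      model <- build_surrogate(cfg)
      model <- stage("train", train_surrogate(model, ds$x, ds$y,
                                              epochs = config$epochs,
                                              batch_size = config$batch_size,
                                              verbose = verbose))
      write_surrogate(model, file.path(config$out_dir, "model"))
      utils::write.table(model$history,
                         file.path(config$out_dir, "history.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      invisible(model)
    },
    cross_validate = {
      ds <- get_dataset()
      rep_seeds <- config$seed + seq_len(config$cv_repeats) - 1L
      report <- stage("cross_validate",
                      cross_validate(ds, config$surrogate, k = config$cv_k,
                                     repeats = config$cv_repeats,
                                     seeds = rep_seeds,
                                     epochs = config$epochs,
                                     batch_size = config$batch_size,
                                     verbose = verbose))
      write_report_tsv(report, file.path(config$out_dir, "cv_report.tsv"))
      invisible(report)
    },
    baseline = {
      ds <- get_dataset()
      folds <- make_folds(ds$manifest, k = max(2L, config$cv_k),
                          seed = config$seed)
      test <- folds == 1L
      pred <- baseline_predict(ds$y[!test, , drop = FALSE], sum(test))
      report <- evaluation_report(ds$y[test, , drop = FALSE], pred,
                                  context = "baseline")
      write_report_tsv(report,
                       file.path(config$out_dir, "baseline_report.tsv"))
      invisible(report)
    },
    prune_predict = {
      model_dir <- file.path(config$out_dir, "model")
      if (!dir.exists(model_dir))
        stop("stage 'prune_predict' failed: no trained model in ",
             model_dir, "; run the train_full recipe first")
      model <- read_surrogate(model_dir)
      n_dom <- (config$window + config$pruning$n_remove - 10L) %/% 2L
      dumbbell <- stage("fixture",
                        generate_dumbbell_chain(n_domain = n_dom,
                                                n_linker = 10L,
                                                seed = config$seed))
      report <- stage("pruning_experiment",
                      pruning_experiment(dumbbell, list(model),
                                         config$pruning,
                                         params = config$params,
                                         input_size = config$window))
      tab <- data.frame(eigenvalue = seq_along(report$eigenvalue_mean),
                        predicted_mean = report$eigenvalue_mean,
                        predicted_sd = report$eigenvalue_sd,
                        true = report$true_eigenvalues)
      utils::write.table(tab,
                         file.path(config$out_dir, "pruning_report.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      invisible(report)
    })
}

#' Command-line entry point
#'
#' Subcommand dispatcher used by the `enmspec` executable script:
#' `enmspec spectrum --pdb FILE [--chain A] [--model beta_gm] [--cutoff 7.5]
#' [--out spectrum.tsv]`, `enmspec decoys --pdb FILE [--chain A]
#' [--window 100] --out DIR`, and `enmspec synth --n 100 --count 10
#' [--compactness 0.7] [--seed 1] --out DIR`.
#'
#' @param args character vector of command-line arguments
#'   (default `commandArgs(trailingOnly = TRUE)`).
#' @return exit status (0 on success), invisibly.
#' @export
enmspec_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste("usage: enmspec <spectrum|decoys|synth> [options]",
                 "  spectrum --pdb FILE [--chain ID] [--model beta_gm]",
                 "           [--cutoff 7.5] [--out spectrum.tsv]",
                 "  decoys   --pdb FILE [--chain ID] [--window 100] --out DIR",
                 "  synth    --n 100 --count 10 [--compactness 0.7]",
                 "           [--seed 1] --out DIR", sep = "\n")
  if (!length(args)) { message(usage); return(invisible(1L)) }
  cmd <- args[1]
  opt <- list()
  rest <- args[-1]
  while (length(rest)) {
    if (!startsWith(rest[1], "--") || length(rest) < 2L)
      stop("malformed option near '", rest[1], "'")
    opt[[substring(rest[1], 3L)]] <- rest[2]
    rest <- rest[-(1:2)]
  }
  get <- function(name, default = NULL) {
    if (!is.null(opt[[name]])) opt[[name]] else default
  }
  switch(cmd,
    spectrum = {
      chain <- read_calpha_trace(get("pdb"), chain_id = get("chain"))
      params <- enm_params(cutoff = as.numeric(get("cutoff", 7.5)),
                           model = get("model", "beta_gm"))
      sp <- enm_spectrum(chain, params = params)
      out <- get("out", "spectrum.tsv")
      tab <- c(paste(c("source_id", paste0("lambda", 1:10),
                       "zero_modes"), collapse = "\t"),
               paste(c(chain$source_id,
                       sprintf("%.8g", sp$eigenvalues),
                       sp$zero_mode_count), collapse = "\t"))
      writeLines(tab, out)
      message("wrote ", out)
    },
    decoys = {
      chain <- read_calpha_trace(get("pdb"), chain_id = get("chain"))
      decoys <- make_decoys(chain, window = as.integer(get("window", 100)))
      dir.create(get("out"), showWarnings = FALSE, recursive = TRUE)
      for (d in decoys)
        write_chain_tsv(d, file.path(get("out"),
                                     sprintf("%s_w%03d.tsv", d$source_id,
                                             d$window_offset)))
      message("wrote ", length(decoys), " decoys to ", get("out"))
    },
    synth = {
      n <- as.integer(get("n", 100)); count <- as.integer(get("count", 10))
      seed <- as.integer(get("seed", 1))
      dir.create(get("out"), showWarnings = FALSE, recursive = TRUE)
      for (i in seq_len(count)) {
        ch <- generate_synthetic_chain(
          n, compactness = as.numeric(get("compactness", 0.7)),
          seed = seed + i)
        write_chain_tsv(ch, file.path(get("out"),
                                      sprintf("synth%04d.tsv", i)))
      }
      message("wrote ", count, " chains to ", get("out"))
    },
    { message("unknown command '", cmd, "'\n", usage); return(invisible(1L)) }
  )
  invisible(0L)
}
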
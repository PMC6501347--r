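#' Hinge centre of a chain
#'
#' Defaults to the C-alpha position of the middle residue by sequence index
#' (0-based index `floor(N / 2)`): for a two-domain protein whose linker sits
#' at the sequence centre this is the mechanical hinge.  Real hinges are
#' structure-specific, so both an explicit residue index and an explicit
#' coordinate override are provided.
#'
#' @param chain a [chain_structure()].
#' @param residue_index optional 0-based residue index override.
#' @param coordinate optional explicit 3-vector override (Angstrom).
#' @return numeric 3-vector.
#' @export
hinge_centre <- function(chain, residue_index = NULL, coordinate = NULL) {
  if (!is.null(coordinate)) {
    stopifnot(length(coordinate) == 3L)
    return(as.numeric(coordinate))
  }
  n <- length(chain)
  stopifnot(n >= 3L)
  if (is.null(residue_index)) residue_index <- n %/% 2L
  stopifnot(residue_index >= 0L, residue_index < n)
  chain$coords[residue_index + 1L, ]
}

#' Residue-pruning scheme
#'
#' Rules for removing `n_remove` residues so a longer chain fits the
#' surrogate's fixed input size:
#' \describe{
#'   \item{random}{uniform random subsets of residues.}
#'   \item{protected_sphere}{uniform subsets, but residues within
#'     `sphere_radius` of the hinge centre can never be removed.}
#'   \item{displaced_sphere}{the control: the protective sphere is centred
#'     on a randomly chosen residue at least `min_centre_displacement` away
#'     from the hinge, so a localized group of residues is protected, but
#'     the wrong one.}
#' }
#' Reference protocol values: remove 20 residues, sphere radius 10 Angstrom,
#' displaced centres at least 20 Angstrom from the hinge, 100 structures per
#' scheme (for the displaced sphere: 10 sphere placements with 10 structures
#' each).
#'
#' @param kind one of `"random"`, `"protected_sphere"`,
#'   `"displaced_sphere"`.
#' @param n_remove residues to remove.
#' @param sphere_radius protective sphere radius, Angstrom.
#' @param min_centre_displacement minimum distance of a displaced sphere
#'   centre from the hinge centre, Angstrom.
#' @param n_structures total pruned structures to generate.
#' @param n_placements sphere placements for the displaced scheme; each
#'   placement yields `n_structures / n_placements` structures
#'   (`placement_mode = "paired"`), or every structure draws its own centre
#'   (`"independent"`).
#' @param placement_mode see above.
#' @param seed integer seed: identical seeds give identical pruned sets.
#' @return an object of class `pruning_scheme`.
#' @export
pruning_scheme <- function(kind = c("random", "protected_sphere",
                                    "displaced_sphere"),
                           n_remove = 20L, sphere_radius = 10,
                           min_centre_displacement = 20,
                           n_structures = 100L, n_placements = 10L,
                           placement_mode = c("paired", "independent"),
                           seed = 1L) {
  kind <- match.arg(kind)
  placement_mode <- match.arg(placement_mode)
  stopifnot(n_remove >= 1L, sphere_radius > 0, min_centre_displacement > 0,
            n_structures >= 1L, n_placements >= 1L)
  structure(list(kind = kind, n_remove = as.integer(n_remove),
                 sphere_radius = sphere_radius,
                 min_centre_displacement = min_centre_displacement,
                 n_structures = as.integer(n_structures),
                 n_placements = as.integer(n_placements),
                 placement_mode = placement_mode,
                 seed = as.integer(seed)),
            class = "pruning_scheme")
}

#' Prune a chain down to the surrogate input size
#'
#' Generates `scheme$n_structures` pruned copies, each keeping residues in
#' their original order with `scheme$n_remove` residues removed according to
#' the scheme.  Pruned chains intentionally contain backbone gaps; they are
#' valid descriptor input (the Coulomb matrix needs no bonding) but are
#' never fed to the elastic-network engine.
#'
#' @param chain a [chain_structure()] with
#'   `length(chain) - n_remove == input_size`.
#' @param scheme a [pruning_scheme()].
#' @param input_size the surrogate input size (default 100).
#' @param centre hinge centre override (3-vector), default
#'   [hinge_centre()] of the chain.
#' @return list of pruned [chain_structure()]s; each carries the kept
#'   residue indices in attribute `kept` and (for sphere schemes) the
#'   sphere centre in attribute `sphere_centre`.
#' @export
prune_chain <- function(chain, scheme, input_size = 100L, centre = NULL) {
  stopifnot(inherits(chain, "chain_structure"),
            inherits(scheme, "pruning_scheme"))
  n <- length(chain)
  if (n - scheme$n_remove != input_size)
    stop("chain length ", n, " minus n_remove ", scheme$n_remove,
         " must equal the surrogate input size ", input_size)
  if (is.null(centre)) centre <- hinge_centre(chain)
  d_hinge <- sqrt(rowSums(sweep(chain$coords, 2L, centre, "-")^2))

  removable_around <- function(ctr) {
    d <- sqrt(rowSums(sweep(chain$coords, 2L, ctr, "-")^2))
    which(d > scheme$sphere_radius)
  }
  draw_one <- function(removable, sphere_centre = NULL) {
    if (length(removable) < scheme$n_remove)
      stop("sphere protects too many residues: only ", length(removable),
           " removable, need ", scheme$n_remove)
    rm_idx <- sort(removable[sample.int(length(removable),
                                        scheme$n_remove)])
    keep <- setdiff(seq_len(n), rm_idx)
    out <- chain_structure(chain$coords[keep, , drop = FALSE],
                           residue_names = chain$residue_names[keep],
                           source_id = paste0(chain$source_id, "_pruned"),
                           orientation = chain$orientation)
    attr(out, "kept") <- keep
    attr(out, "sphere_centre") <- sphere_centre
    out
  }

  with_seed(scheme$seed, {
    switch(scheme$kind,
      random = replicate(scheme$n_structures, draw_one(seq_len(n)),
                         simplify = FALSE),
      protected_sphere = {
        removable <- removable_around(centre)
        replicate(scheme$n_structures, draw_one(removable, centre),
                  simplify = FALSE)
      },
      displaced_sphere = {
        candidates <- which(d_hinge >= scheme$min_centre_displacement)
        if (!length(candidates))
          stop("no residue at least ", scheme$min_centre_displacement,
               " Angstrom from the hinge centre: protein too small for ",
               "the displaced-sphere control")
        if (scheme$placement_mode == "paired") {
          per <- scheme$n_structures %/% scheme$n_placements
          if (per * scheme$n_placements != scheme$n_structures)
            stop("n_structures must be a multiple of n_placements")
          out <- list()
          for (p in seq_len(scheme$n_placements)) {
            ctr <- chain$coords[candidates[sample.int(length(candidates),
                                                      1L)], ]
            removable <- removable_around(ctr)
            out <- c(out, replicate(per, draw_one(removable, ctr),
                                    simplify = FALSE))
          }
          out
        } else {
          replicate(scheme$n_structures, {
            ctr <- chain$coords[candidates[sample.int(length(candidates),
                                                      1L)], ]
            draw_one(removable_around(ctr), ctr)
          }, simplify = FALSE)
        }
      })
  })
}

#' Run a pruning experiment against the full-structure spectrum
#'
#' The ground truth is the beta-Gaussian spectrum of the *full* chain.  Each
#' pruned structure is encoded as a Coulomb matrix and fed to every network
#' in the ensemble; the report gives the per-eigenvalue mean and standard
#' deviation of the predictions over structures x networks, and the overall
#' average MAPE of all predictions against the true spectrum.  An ensemble
#' of one oracle predictor (a function returning the true spectrum) can be
#' substituted to validate the harness.
#'
#' @param chain the full-length [chain_structure()].
#' @param models list of `trained_surrogate`s (or functions taking a
#'   descriptor array and returning a prediction matrix).
#' @param scheme a [pruning_scheme()].
#' @param params an [enm_params()] for the true spectrum.
#' @param input_size surrogate input size.
#' @param centre hinge centre override.
#' @return an object of class `pruning_report` with fields
#'   `eigenvalue_mean`, `eigenvalue_sd`, `true_eigenvalues`,
#'   `overall_mape`, `scheme`, `n_predictions`.
#' @export
pruning_experiment <- function(chain, models, scheme,
                               params = enm_params(), input_size = 100L,
                               centre = NULL) {
  stopifnot(length(models) >= 1L)
  truth <- enm_spectrum(chain, params = params)
  pruned <- prune_chain(chain, scheme, input_size = input_size,
                        centre = centre)
  x <- simplify2array(lapply(pruned, function(p)
    unclass(coulomb_matrix(p))))                   # N x N x structures
  preds <- lapply(models, function(m) {
    if (is.function(m)) m(x) else predict(m, x)
  })
  all_preds <- do.call(rbind, preds)               # (structures*models) x 10
  true_mat <- matrix(truth$eigenvalues, nrow = nrow(all_preds),
                     ncol = length(truth$eigenvalues), byrow = TRUE)
  structure(list(eigenvalue_mean = colMeans(all_preds),
                 eigenvalue_sd = apply(all_preds, 2L, stats::sd),
                 true_eigenvalues = truth$eigenvalues,
                 overall_mape = mean(per_sample_mape(true_mat, all_preds)),
                 scheme = scheme,
                 n_predictions = nrow(all_preds)),
            class = "pruning_report")
}

#' @export
print.pruning_report <- function(x, ...) {
  cat(sprintf(paste0("<pruning_report> %s: %d predictions, overall MAPE ",
                     "%.2f%%\n"),
              x$scheme$kind, x$n_predictions, x$overall_mape))
  invisible(x)
}
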
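#' Coulomb-matrix descriptor of a C-alpha trace
#'
#' The N x N matrix with `C[I, J] = 1 / |R_I - R_J|` off the diagonal and 0
#' on it (units 1/Angstrom): a global, rotation/translation-invariant
#' encoding of the structure that the convolutional surrogate consumes
#' directly, with no charge term and no preprocessing.  Rows follow sequence
#' order -- deliberately *not* the sorted-norm canonicalization used in
#' cheminformatics, because reversal-augmented training relies on the
#' descriptor being order-dependent (the descriptor of a reversed chain is
#' the anti-transpose of the original).
#'
#' @param chain a [chain_structure()] or a coordinate matrix.
#' @return an object of class `coulomb_matrix`: the numeric matrix, with
#'   provenance (`source_id`, `window_offset`, `orientation`) attached as
#'   attributes when a chain is given.
#' @export
coulomb_matrix <- function(chain) {
  xy <- as_coords(chain)
  n <- nrow(xy)
  d <- as.matrix(stats::dist(xy))
  off <- d[upper.tri(d)]
  if (any(off < 1e-9)) {
    idx <- which(upper.tri(d) & d < 1e-9, arr.ind = TRUE)
    stop("coincident residues (", idx[1, 1], ", ", idx[1, 2],
         "): Coulomb matrix undefined")
  }
  cm <- 1 / d
  diag(cm) <- 0
  dimnames(cm) <- NULL
  structure(cm, class = c("coulomb_matrix", "matrix", "array"),
            source_id = if (inherits(chain, "chain_structure"))
              chain$source_id else NA_character_,
            window_offset = if (inherits(chain, "chain_structure"))
              chain$window_offset else NA_integer_,
            orientation = if (inherits(chain, "chain_structure"))
              chain$orientation else NA_character_)
}

#' @export
print.coulomb_matrix <- function(x, ...) {
  cat(sprintf("<coulomb_matrix> %dx%d, source %s\n", nrow(x), ncol(x),
              attr(x, "source_id")))
  invisible(x)
}

#' Anti-transpose of a matrix (flip both axes)
#'
#' The descriptor of a reversed chain equals the anti-transpose of the
#' descriptor of the direct chain, so reversed inputs can be derived without
#' recomputing distances.
#'
#' @param m a matrix.
#' @return the matrix flipped along both axes.
#' @export
anti_transpose <- function(m) {
  m[rev(seq_len(nrow(m))), rev(seq_len(ncol(m))), drop = FALSE]
}

#' Assemble a descriptor/target dataset from chains
#'
#' Computes the Coulomb matrix and (optionally) the beta-Gaussian spectrum of
#' every chain, with the reversed copy of each chain appended when
#' `augment_reversed` is TRUE.  Reversed copies reuse the direct spectrum
#' (the spectrum is reversal-invariant) and the anti-transposed descriptor,
#' so targets are computed once per direct structure.
#'
#' @param chains list of [chain_structure()]s, all of one length.
#' @param params an [enm_params()] used for the targets.
#' @param targets compute spectra?  Set FALSE for prediction-only datasets.
#' @param augment_reversed append reversed copies?
#' @param n_modes eigenvalues per target.
#' @param drop_invalid drop chains with invalid targets: a spectrum without
#'   exactly 6 zero modes (mechanically floppy structures, whose lowest
#'   "non-zero" eigenvalues are numerical noise), or a lowest eigenvalue
#'   below `min_eigenvalue`.  A message reports how many were dropped.
#' @param min_eigenvalue validity floor for the lowest eigenvalue (model
#'   units; only used with `drop_invalid = TRUE`).  The relative-error loss
#'   weights a target by its reciprocal, so quasi-floppy structures with
#'   lambda_1 near zero destabilise training; real protein sets have their
#'   eigenvalue distribution bounded away from zero.
#' @return list with `x` (array n_samples x N x N), `y` (matrix n_samples x
#'   n_modes or NULL) and `manifest` (data.frame sample_id, source_id,
#'   window_offset, orientation).  Direct samples come first, then the
#'   reversed copies in the same order.
#' @export
build_dataset <- function(chains, params = enm_params(), targets = TRUE,
                          augment_reversed = TRUE, n_modes = 10L,
                          drop_invalid = FALSE, min_eigenvalue = 0) {
  stopifnot(length(chains) > 0)
  sizes <- vapply(chains, length, integer(1))
  if (length(unique(sizes)) != 1L)
    stop("all chains must have the same length; got ",
         paste(unique(sizes), collapse = ", "))
  n <- sizes[1]
  n_direct <- length(chains)
  x_direct <- array(NA_real_, c(n_direct, n, n))
  y <- if (targets) matrix(NA_real_, n_direct, n_modes) else NULL
  zm_ok <- rep(TRUE, n_direct)
  for (s in seq_len(n_direct)) {
    x_direct[s, , ] <- unclass(coulomb_matrix(chains[[s]]))
    if (targets) {
      sp <- suppressWarnings(enm_spectrum(chains[[s]], n_modes = n_modes,
                                          params = params))
      y[s, ] <- sp$eigenvalues
      zm_ok[s] <- sp$zero_mode_count == 6L &&
        sp$eigenvalues[1] >= min_eigenvalue
    }
  }
  if (targets && drop_invalid && !all(zm_ok)) {
    message("dropping ", sum(!zm_ok),
            " chain(s) with invalid targets (zero-mode count != 6 or ",
            "lambda_1 < ", min_eigenvalue, ")")
    x_direct <- x_direct[zm_ok, , , drop = FALSE]
    y <- y[zm_ok, , drop = FALSE]
    chains <- chains[zm_ok]
    n_direct <- length(chains)
  } else if (targets && !all(zm_ok)) {
    warning(sum(!zm_ok), " chain(s) without exactly 6 zero modes kept in ",
            "the dataset; consider drop_invalid = TRUE")
  }
  man_row <- function(ch) data.frame(sample_id = sample_key(ch),
                                     source_id = ch$source_id,
                                     window_offset = ch$window_offset,
                                     orientation = ch$orientation,
                                     stringsAsFactors = FALSE)
  manifest <- do.call(rbind, lapply(chains, man_row))
  if (augment_reversed) {
    x_rev <- x_direct[, rev(seq_len(n)), rev(seq_len(n)), drop = FALSE]
    x <- array(NA_real_, c(2L * n_direct, n, n))
    x[seq_len(n_direct), , ] <- x_direct
    x[n_direct + seq_len(n_direct), , ] <- x_rev
    if (targets) y <- rbind(y, y)
    manifest <- rbind(manifest,
                      do.call(rbind, lapply(chains, function(ch)
                        man_row(reverse_chain(ch)))))
  } else {
    x <- x_direct
  }
  rownames(manifest) <- NULL
  list(x = x, y = y, manifest = manifest)
}

sample_key <- function(chain) {
  paste(chain$source_id,
        ifelse(is.na(chain$window_offset), "full", chain$window_offset),
        chain$orientation, sep = "|")
}

#' Write / read a descriptor dataset as plain text
#'
#' One directory with `manifest.tsv`, flattened descriptors in
#' `descriptors.tsv` (one row per sample, row-major) and optional targets in
#' `targets.tsv`.
#'
#' @param dataset a list as returned by [build_dataset()].
#' @param dir output directory (created if needed).
#' @return `write_dataset` returns `dir` invisibly; `read_dataset` the
#'   dataset list.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(dataset$manifest, file.path(dir, "manifest.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  n <- dim(dataset$x)[2]
  flat <- matrix(aperm(dataset$x, c(1, 3, 2)), nrow = dim(dataset$x)[1])
  utils::write.table(format(flat, digits = 10, trim = TRUE),
                     file.path(dir, "descriptors.tsv"), sep = "\t",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  writeLines(as.character(n), file.path(dir, "descriptor_size.txt"))
  if (!is.null(dataset$y))
    utils::write.table(dataset$y, file.path(dir, "targets.tsv"), sep = "\t",
                       row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  manifest <- utils::read.delim(file.path(dir, "manifest.tsv"),
                                stringsAsFactors = FALSE)
  n <- as.integer(readLines(file.path(dir, "descriptor_size.txt")))
  flat <- as.matrix(utils::read.delim(file.path(dir, "descriptors.tsv"),
                                      header = FALSE))
  x <- aperm(array(flat, c(nrow(flat), n, n)), c(1, 3, 2))
  y <- NULL
  if (file.exists(file.path(dir, "targets.tsv")))
    y <- as.matrix(utils::read.delim(file.path(dir, "targets.tsv"),
                                     header = FALSE))
  dimnames(y) <- NULL
  list(x = x, y = y, manifest = manifest)
}
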
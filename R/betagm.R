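#' Elastic network model parameters
#'
#' One parameter set drives both supported models: the plain C-alpha
#' anisotropic network model (`"anm_calpha"`) and the beta-Gaussian model
#' (`"beta_gm"`), in which effective C-beta centroids are attached to the
#' local C-alpha geometry and then integrated out analytically.  Spring
#' constants are in (energy unit)/Angstrom^2; only their ratios matter for
#' the shape of the spectrum, and a common scale factor scales all
#' eigenvalues linearly.  Eigenvalues are therefore reported in model units.
#'
#' @param cutoff interaction cutoff radius Rc in Angstrom (default 7.5).
#' @param k_alpha_alpha,k_alpha_beta,k_beta_beta spring constants for the
#'   three contact classes.
#' @param k_backbone spring constant for bonded consecutive C-alpha pairs,
#'   which are connected regardless of the cutoff.
#' @param cbeta_offset distance (Angstrom) of the C-beta centroid from its
#'   C-alpha along the local bisector direction.
#' @param model `"beta_gm"` or `"anm_calpha"`.
#' @return an object of class `enm_params`.
#' @export
enm_params <- function(cutoff = 7.5, k_alpha_alpha = 1.0, k_alpha_beta = 1.0,
                       k_beta_beta = 1.0, k_backbone = 1.0,
                       cbeta_offset = 3.0,
                       model = c("beta_gm", "anm_calpha")) {
  model <- match.arg(model)
  stopifnot(cutoff > 0, cbeta_offset > 0,
            k_alpha_alpha >= 0, k_alpha_beta >= 0, k_beta_beta >= 0,
            k_backbone >= 0)
  structure(list(cutoff = cutoff, k_alpha_alpha = k_alpha_alpha,
                 k_alpha_beta = k_alpha_beta, k_beta_beta = k_beta_beta,
                 k_backbone = k_backbone, cbeta_offset = cbeta_offset,
                 model = model),
            class = "enm_params")
}

as_coords <- function(x) {
  if (inherits(x, "chain_structure")) x$coords else {
    m <- as.matrix(x); storage.mode(m) <- "double"; m
  }
}

# pair table (i, j, k) with i < j for a set of sites:
# bonded pairs always present at k_bond, all other pairs at k_contact iff the
# reference distance is below the cutoff.  `bonded` is a 2-column matrix.
contact_pairs <- function(coords, cutoff, k_contact, bonded = NULL,
                          k_bond = k_contact) {
  n <- nrow(coords)
  d <- as.matrix(stats::dist(coords))
  sel <- which(upper.tri(d) & d < cutoff, arr.ind = TRUE)
  pairs <- data.frame(i = sel[, 1], j = sel[, 2],
                      k = rep(k_contact, nrow(sel)))
  if (!is.null(bonded) && nrow(bonded)) {
    bi <- pmin(bonded[, 1], bonded[, 2])
    bj <- pmax(bonded[, 1], bonded[, 2])
    key <- paste(pairs$i, pairs$j)
    bkey <- paste(bi, bj)
    pairs <- pairs[!key %in% bkey, , drop = FALSE]
    pairs <- rbind(pairs, data.frame(i = bi, j = bj, k = k_bond))
  }
  pairs[pairs$k > 0, , drop = FALSE]
}

#' Total harmonic pair energy of a displaced configuration
#'
#' The single-parameter harmonic spring energy
#' `sum over pairs of (k/2) (|r_ij| - |r_ij^0|)^2`, with the pair list fixed
#' by the reference configuration and the cutoff.  Used as the
#' finite-difference oracle for the analytic Hessians.
#'
#' @param coords displaced coordinates (matrix, one row per site).
#' @param ref_coords reference coordinates defining pairs and rest lengths.
#' @param params an [enm_params()]; `k_alpha_alpha` is the spring constant
#'   when no explicit pair table is given.
#' @param pairs optional data.frame (i, j, k) overriding the cutoff-derived
#'   pair list.
#' @return scalar energy in model units.
#' @export
pair_energy_total <- function(coords, ref_coords, params = enm_params(),
                              pairs = NULL) {
  coords <- as_coords(coords); ref_coords <- as_coords(ref_coords)
  if (!identical(dim(coords), dim(ref_coords)))
    stop("coords and ref_coords differ in shape")
  if (is.null(pairs))
    pairs <- contact_pairs(ref_coords, params$cutoff, params$k_alpha_alpha)
  if (!nrow(pairs)) return(0)
  dnow <- sqrt(rowSums((coords[pairs$i, , drop = FALSE] -
                        coords[pairs$j, , drop = FALSE])^2))
  dref <- sqrt(rowSums((ref_coords[pairs$i, , drop = FALSE] -
                        ref_coords[pairs$j, , drop = FALSE])^2))
  sum(pairs$k / 2 * (dnow - dref)^2)
}

# dense 3n x 3n Hessian from a pair table; site i occupies rows/cols
# 3i-2 .. 3i.  Off-diagonal block for pair (i,j):
#   -k (r_mu r_nu) / |r|^2  with r = ri - rj;
# diagonal blocks enforce translation invariance (rows sum to zero).
hessian_from_pairs <- function(coords, pairs) {
  n <- nrow(coords)
  H <- matrix(0, 3 * n, 3 * n)
  for (p in seq_len(nrow(pairs))) {
    i <- pairs$i[p]; j <- pairs$j[p]; k <- pairs$k[p]
    d <- coords[i, ] - coords[j, ]
    d2 <- sum(d^2)
    if (d2 < 1e-16)
      stop("coincident sites in interacting pair (", i, ", ", j, ")")
    blk <- -k * tcrossprod(d) / d2
    ri <- (3 * i - 2):(3 * i); rj <- (3 * j - 2):(3 * j)
    H[ri, rj] <- H[ri, rj] + blk
    H[rj, ri] <- H[rj, ri] + blk
    H[ri, ri] <- H[ri, ri] - blk
    H[rj, rj] <- H[rj, rj] - blk
  }
  H
}

new_effective_hessian <- function(H, params, n_sites, model) {
  structure(list(matrix = H, params = params, n_sites = n_sites,
                 model = model),
            class = "effective_hessian")
}

#' @export
print.effective_hessian <- function(x, ...) {
  cat(sprintf("<effective_hessian> %s, %d sites (%dx%d), cutoff %.2f A\n",
              x$model, x$n_sites, nrow(x$matrix), ncol(x$matrix),
              x$params$cutoff))
  invisible(x)
}

#' Anisotropic network model Hessian of a C-alpha trace
#'
#' Builds the 3Nx3N ANM Hessian: a harmonic spring for every site pair
#' closer than the cutoff (constant `k_alpha_alpha`), and, for chain input,
#' bonded springs between consecutive C-alphas (constant `k_backbone`)
#' regardless of the cutoff.
#'
#' @param x a [chain_structure()] or a coordinate matrix (one row per site;
#'   bare matrices get no backbone bonds unless `backbone = TRUE`).
#' @param params an [enm_params()].
#' @param backbone add bonded springs between consecutive sites?
#' @return an `effective_hessian`.
#' @export
build_anm_hessian <- function(x, params = enm_params(),
                              backbone = inherits(x, "chain_structure")) {
  coords <- as_coords(x)
  n <- nrow(coords)
  if (n < 2L) stop("need at least 2 sites")
  bonded <- if (backbone && n >= 2L)
    cbind(seq_len(n - 1L), seq_len(n - 1L) + 1L) else NULL
  pairs <- contact_pairs(coords, params$cutoff, params$k_alpha_alpha,
                         bonded = bonded, k_bond = params$k_backbone)
  new_effective_hessian(hessian_from_pairs(coords, pairs), params, n,
                        "anm_calpha")
}

#' Place effective C-beta centroids on a C-alpha trace
#'
#' Each internal, non-glycine residue i receives a centroid at
#' `r_i + a * v / |v|` with `v = 2 r_i - r_(i-1) - r_(i+1)` and `a` the
#' `cbeta_offset`: the centroid sits in the plane of the local trace, along
#' the bisector pointing away from the chain.  Glycines and the two terminal
#' residues carry no centroid; a locally collinear trace (|v| below 1e-6
#' Angstrom) drops the centroid with a warning.  The returned Jacobians are
#' the exact derivatives of the placement map with respect to the three
#' parent C-alpha positions, used to reduce the full Hessian to C-alpha
#' coordinates.
#'
#' @param chain a [chain_structure()] (length >= 3).
#' @param params an [enm_params()].
#' @return list with `positions` (N x 3 matrix, NA rows where no centroid)
#'   and `jacobians` (list of 3 x 9 matrices over the displacements of
#'   C-alphas i-1, i, i+1; NULL where no centroid).
#' @export
place_cbeta <- function(chain, params = enm_params()) {
  stopifnot(inherits(chain, "chain_structure"))
  xy <- chain$coords
  n <- nrow(xy)
  if (n < 3L) stop("need at least 3 residues to place C-beta centroids")
  a <- params$cbeta_offset
  positions <- matrix(NA_real_, n, 3L)
  jacobians <- vector("list", n)
  dropped <- integer(0)
  for (i in seq(2L, n - 1L)) {
    if (chain$residue_names[i] == "GLY") next
    v <- 2 * xy[i, ] - xy[i - 1L, ] - xy[i + 1L, ]
    nv <- sqrt(sum(v^2))
    if (nv < 1e-6) { dropped <- c(dropped, i); next }
    u <- v / nv
    positions[i, ] <- xy[i, ] + a * u
    P <- (diag(3) - tcrossprod(u)) / nv       # d(v/|v|)/dv
    jacobians[[i]] <- cbind(-a * P, diag(3) + 2 * a * P, -a * P)
  }
  if (length(dropped))
    warning("locally collinear trace: no C-beta centroid at residue(s) ",
            paste(dropped, collapse = ", "))
  list(positions = positions, jacobians = jacobians)
}

# pair inventory of the full (C-alpha + C-beta) network.  Site order:
# alphas 1..n, then betas in residue order.  Returns list(pairs, beta_idx)
# where beta_idx maps beta site number -> parent residue.
betagm_site_pairs <- function(chain, placement, params) {
  xy <- chain$coords
  n <- nrow(xy)
  beta_idx <- which(!is.na(placement$positions[, 1]))
  sites <- rbind(xy, placement$positions[beta_idx, , drop = FALSE])
  m <- length(beta_idx)
  is_beta <- c(rep(FALSE, n), rep(TRUE, m))
  d <- as.matrix(stats::dist(sites))
  sel <- which(upper.tri(d) & d < params$cutoff, arr.ind = TRUE)
  i <- sel[, 1]; j <- sel[, 2]
  kind <- is_beta[i] + is_beta[j]           # 0 = aa, 1 = ab, 2 = bb
  k <- c(params$k_alpha_alpha, params$k_alpha_beta,
         params$k_beta_beta)[kind + 1L]
  # consecutive alphas: bonded, replace any contact spring
  consec <- (kind == 0L) & (abs(i - j) == 1L)
  k[consec] <- params$k_backbone
  pairs <- data.frame(i = i, j = j, k = k)
  missing_bonds <- which(!(paste(seq_len(n - 1L), seq_len(n - 1L) + 1L) %in%
                           paste(i[consec], j[consec])))
  if (length(missing_bonds))
    pairs <- rbind(pairs,
                   data.frame(i = missing_bonds, j = missing_bonds + 1L,
                              k = params$k_backbone))
  list(pairs = pairs[pairs$k > 0, , drop = FALSE], sites = sites,
       beta_idx = beta_idx)
}

#' Effective C-alpha Hessian of the beta-Gaussian model
#'
#' Assembles the anisotropic Hessian of the full C-alpha + C-beta network
#' (backbone bonds between consecutive C-alphas plus all cutoff contacts in
#' the three classes alpha-alpha, alpha-beta, beta-beta) and then eliminates
#' the C-beta displacements through the linear placement map
#' `x_beta = A x_alpha`, giving `M~ = B' M B` with `B = [I; A]`.  The result
#' is a 3Nx3N quadratic form in C-alpha displacements only, with the same
#' translation/rotation null space as the full model.
#'
#' @param chain a [chain_structure()] (length >= 4).
#' @param params an [enm_params()].
#' @return an `effective_hessian` with `model = "beta_gm"`.
#' @export
build_betagm_hessian <- function(chain, params = enm_params()) {
  stopifnot(inherits(chain, "chain_structure"))
  n <- length(chain)
  if (n < 4L) stop("need at least 4 residues")
  placement <- place_cbeta(chain, params)
  sp <- betagm_site_pairs(chain, placement, params)
  # for connectivity, every centroid is slaved to its parent C-alpha even
  # when its spring constants are zero (the limiting C-alpha-only case)
  conn_pairs <- rbind(sp$pairs[c("i", "j")],
                      data.frame(i = seq_len(n - 1L),
                                 j = seq_len(n - 1L) + 1L),
                      data.frame(i = sp$beta_idx,
                                 j = n + seq_along(sp$beta_idx)))
  if (!sites_connected(nrow(sp$sites), conn_pairs))
    stop("elastic network is disconnected at cutoff ", params$cutoff,
         " Angstrom; increase the cutoff or reject the structure")
  H <- hessian_from_pairs(sp$sites, sp$pairs)
  m <- length(sp$beta_idx)
  B <- matrix(0, 3 * (n + m), 3 * n)
  B[seq_len(3 * n), ] <- diag(3 * n)
  for (b in seq_len(m)) {
    i <- sp$beta_idx[b]
    J <- placement$jacobians[[i]]            # 3 x 9 over alphas i-1, i, i+1
    rows <- 3 * n + (3 * b - 2):(3 * b)
    cols <- (3 * (i - 1) - 2):(3 * (i + 1))
    B[rows, cols] <- J
  }
  Ht <- crossprod(B, H %*% B)
  Ht <- (Ht + t(Ht)) / 2
  new_effective_hessian(Ht, params, n, "beta_gm")
}

sites_connected <- function(n_sites, pairs) {
  seen <- logical(n_sites); seen[1] <- TRUE
  adj <- split(c(pairs$j, pairs$i), c(pairs$i, pairs$j))
  frontier <- 1L
  while (length(frontier)) {
    nb <- unique(unlist(adj[as.character(frontier)], use.names = FALSE))
    nb <- nb[!seen[nb]]
    seen[nb] <- TRUE
    frontier <- nb
  }
  all(seen)
}

#' Build the Hessian selected by `params$model`
#'
#' @param chain a [chain_structure()].
#' @param params an [enm_params()].
#' @return an `effective_hessian`.
#' @export
enm_hessian <- function(chain, params = enm_params()) {
  switch(params$model,
         beta_gm = build_betagm_hessian(chain, params),
         anm_calpha = build_anm_hessian(chain, params))
}

#' Composed beta-Gaussian energy of displaced C-alpha coordinates
#'
#' Energy of the full C-alpha + C-beta spring network when the C-alphas are
#' displaced and the C-beta centroids are *recomputed* from the displaced
#' trace through the nonlinear placement map.  The pair inventory and rest
#' lengths are fixed at the reference chain.  This is the independent oracle
#' whose finite-difference Hessian must match [build_betagm_hessian()].
#'
#' @param chain the reference [chain_structure()].
#' @param displaced_coords displaced C-alpha coordinates (N x 3).
#' @param params an [enm_params()].
#' @return scalar energy.
#' @export
betagm_energy <- function(chain, displaced_coords, params = enm_params()) {
  displaced_coords <- as_coords(displaced_coords)
  placement <- place_cbeta(chain, params)
  sp <- betagm_site_pairs(chain, placement, params)
  # recompute beta positions from the displaced trace (same residues)
  disp_chain <- chain_structure(displaced_coords,
                                residue_names = chain$residue_names,
                                source_id = chain$source_id,
                                validate = FALSE)
  disp_pl <- suppressWarnings(place_cbeta(disp_chain, params))
  disp_beta <- disp_pl$positions[sp$beta_idx, , drop = FALSE]
  if (anyNA(disp_beta))
    stop("displacement made a C-beta placement degenerate")
  disp_sites <- rbind(displaced_coords, disp_beta)
  pair_energy_total(disp_sites, sp$sites, params, pairs = sp$pairs)
}

#' Lowest non-zero eigenvalues of an elastic-network Hessian
#'
#' Full symmetric eigendecomposition; eigenvalues below
#' `1e-8 * max(eigenvalue)` count as zero modes (rigid translations and
#' rotations: exactly 6 for a connected, non-collinear structure).  Returns
#' the `n_modes` smallest eigenvalues above that tolerance, ascending -- the
#' regression target of the surrogate.
#'
#' @param x an `effective_hessian` or a [chain_structure()] (in which case
#'   the Hessian named by `params$model` is built first).
#' @param n_modes number of non-zero eigenvalues to return (default 10).
#' @param params an [enm_params()], used when `x` is a chain.
#' @param vectors keep the corresponding eigenvectors?
#' @return an object of class `spectrum_target` with fields `eigenvalues`,
#'   `zero_mode_count`, provenance (`source_id`, `window_offset`,
#'   `orientation`) and optionally `vectors`.
#' @export
enm_spectrum <- function(x, n_modes = 10L, params = enm_params(),
                         vectors = FALSE) {
  prov <- list(source_id = NA_character_, window_offset = NA_integer_,
               orientation = NA_character_)
  if (inherits(x, "chain_structure")) {
    prov <- x[c("source_id", "window_offset", "orientation")]
    x <- enm_hessian(x, params)
  }
  stopifnot(inherits(x, "effective_hessian"))
  eig <- eigen(x$matrix, symmetric = TRUE)
  vals <- rev(eig$values)                       # ascending
  tol <- 1e-8 * max(abs(vals))
  zero_modes <- sum(vals < tol)
  if (zero_modes != 6L)
    warning("expected 6 zero modes, found ", zero_modes,
            " (collinear or disconnected structure?)")
  nz <- which(vals >= tol)
  if (length(nz) < n_modes)
    stop("only ", length(nz), " non-zero eigenvalues, need ", n_modes)
  keep <- nz[seq_len(n_modes)]
  out <- structure(
    list(eigenvalues = vals[keep], zero_mode_count = zero_modes,
         source_id = prov$source_id, window_offset = prov$window_offset,
         orientation = prov$orientation),
    class = "spectrum_target")
  if (vectors)
    out$vectors <- eig$vectors[, rev(seq_along(vals))[keep], drop = FALSE]
  out
}

#' @export
print.spectrum_target <- function(x, ...) {
  cat(sprintf("<spectrum_target> %s: %d zero modes; lowest %d eigenvalues:\n",
              x$source_id, x$zero_mode_count, length(x$eigenvalues)))
  print(signif(x$eigenvalues, 5))
  invisible(x)
}
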
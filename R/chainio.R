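#' Ordered C-alpha trace of a single protein chain
#'
#' `chain_structure` is the unit every stage of the pipeline consumes: an
#' ordered list of C-alpha positions (in Angstrom) together with 3-letter
#' residue names (glycines matter, because the beta-Gaussian model places no
#' C-beta centroid on them), an orientation flag and, for decoys cut out of a
#' longer parent, the 0-based offset of the window within the parent chain.
#'
#' @param coords numeric matrix with one row per residue and columns x, y, z
#'   (Angstrom).
#' @param residue_names character vector of 3-letter residue codes, one per
#'   residue.  Defaults to `"ALA"` everywhere.
#' @param source_id text label identifying the parent structure.
#' @param orientation `"direct"` or `"reversed"`.
#' @param window_offset 0-based index of the first residue within the parent
#'   chain, or `NA` for a full chain.
#' @param validate check invariants (finite coordinates, matching lengths,
#'   at least 4 residues)?
#' @return an object of class `chain_structure`.
#' @export
chain_structure <- function(coords, residue_names = NULL,
                            source_id = "chain", orientation = "direct",
                            window_offset = NA_integer_, validate = TRUE) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (ncol(coords) != 3L)
    stop("'coords' must have 3 columns (x, y, z)")
  n <- nrow(coords)
  if (is.null(residue_names)) residue_names <- rep("ALA", n)
  orientation <- match.arg(orientation, c("direct", "reversed"))
  obj <- structure(
    list(source_id = as.character(source_id),
         residue_names = as.character(residue_names),
         coords = unname(coords),
         orientation = orientation,
         window_offset = as.integer(window_offset)),
    class = "chain_structure")
  if (validate) validate_chain(obj)
  obj
}

#' Validate the invariants of a chain structure
#'
#' @param chain a [chain_structure()].
#' @param min_bond,max_bond acceptable consecutive C-alpha distance bounds in
#'   Angstrom; a distance outside the bounds flags a chain break.
#' @param check_breaks error on chain breaks?
#' @return the chain, invisibly; errors describe the first violation.
#' @export
validate_chain <- function(chain, min_bond = 2.5, max_bond = 4.5,
                           check_breaks = FALSE) {
  stopifnot(inherits(chain, "chain_structure"))
  n <- nrow(chain$coords)
  if (length(chain$residue_names) != n)
    stop("residue_names and coords disagree in length")
  if (n < 4L)
    stop("a chain needs at least 4 residues, got ", n)
  if (!all(is.finite(chain$coords)))
    stop("non-finite coordinates in chain '", chain$source_id, "'")
  if (check_breaks) {
    d <- consecutive_distances(chain)
    bad <- which(d <= min_bond | d >= max_bond)
    if (length(bad))
      stop("chain break (consecutive C-alpha distance ", round(d[bad[1]], 2),
           " Angstrom) after residue ", bad[1], " of '", chain$source_id, "'")
  }
  invisible(chain)
}

#' @export
print.chain_structure <- function(x, ...) {
  cat(sprintf("<chain_structure> %s: %d residues, %s orientation%s\n",
              x$source_id, nrow(x$coords), x$orientation,
              if (is.na(x$window_offset)) ""
              else sprintf(", window offset %d", x$window_offset)))
  invisible(x)
}

#' @export
length.chain_structure <- function(x) nrow(x$coords)

consecutive_distances <- function(chain) {
  xy <- chain$coords
  sqrt(rowSums((xy[-1L, , drop = FALSE] - xy[-nrow(xy), , drop = FALSE])^2))
}

chain_break_positions <- function(chain, min_bond = 2.5, max_bond = 4.5) {
  d <- consecutive_distances(chain)
  which(d <= min_bond | d >= max_bond)   # break between residue i and i+1
}

#' Read the C-alpha trace of one chain from PDB-format text
#'
#' Parses ATOM records (fixed-width PDB columns) of the first MODEL, keeps one
#' C-alpha per residue (altloc "A" preferred, otherwise the first one seen),
#' ignores HETATM and non-CA atoms, and preserves file order of residues
#' (insertion codes included).
#'
#' @param pdb path to a PDB file, or a character vector of PDB lines.
#' @param chain_id 1-character chain identifier, or `NULL` to auto-select when
#'   the file holds exactly one chain.
#' @return a [chain_structure()] whose `source_id` is `"<basename>_<chain>"`
#'   for file input.
#' @export
read_calpha_trace <- function(pdb, chain_id = NULL) {
  src <- "pdb"
  if (length(pdb) == 1L && !grepl("\n", pdb) && file.exists(pdb)) {
    src <- sub("\\.(pdb|ent)$", "", basename(pdb), ignore.case = TRUE)
    lines <- readLines(pdb, warn = FALSE)
  } else {
    lines <- unlist(strsplit(pdb, "\n", fixed = TRUE), use.names = FALSE)
  }
  # first MODEL only
  endmdl <- grep("^ENDMDL", lines)
  if (length(endmdl)) lines <- lines[seq_len(endmdl[1] - 1L)]
  atoms <- lines[startsWith(lines, "ATOM")]
  if (!length(atoms)) stop("no ATOM records found")

  fld <- function(a, b) trimws(substr(atoms, a, b))
  name    <- fld(13, 16)
  altloc  <- fld(17, 17)
  resname <- fld(18, 20)
  ch      <- substr(atoms, 22, 22)
  resid   <- paste0(fld(23, 26), fld(27, 27))   # resSeq + insertion code

  is_ca <- name == "CA"
  if (!any(is_ca)) stop("no CA atoms in ATOM records")
  available <- unique(ch[is_ca])
  if (is.null(chain_id)) {
    if (length(available) > 1L)
      stop("multiple chains present (", paste(available, collapse = ", "),
           "); pass 'chain_id'")
    chain_id <- available
  }
  if (!chain_id %in% available)
    stop("chain '", chain_id, "' not found; available chains: ",
         paste(available, collapse = ", "))

  keep <- is_ca & ch == chain_id
  # residues of the chain in file order, from any atom of the chain
  res_order <- unique(resid[ch == chain_id])
  ca_res <- resid[keep]
  missing_ca <- setdiff(res_order, ca_res)
  if (length(missing_ca))
    stop("residue(s) without a CA atom in chain ", chain_id, ": ",
         paste(utils::head(missing_ca, 5L), collapse = ", "))

  idx <- which(keep)
  # altloc priority: "A" or blank first, then file order
  pri <- ifelse(altloc[idx] %in% c("", "A"), 0L, 1L)
  idx <- idx[order(match(resid[idx], res_order), pri,
                   seq_along(idx))]
  idx <- idx[!duplicated(resid[idx])]

  xyz <- cbind(as.numeric(substr(atoms[idx], 31, 38)),
               as.numeric(substr(atoms[idx], 39, 46)),
               as.numeric(substr(atoms[idx], 47, 54)))
  chain_structure(xyz, residue_names = resname[idx],
                  source_id = paste0(src, "_", chain_id))
}

random_unit_vector <- function() {
  repeat {
    v <- stats::rnorm(3)
    nv <- sqrt(sum(v^2))
    if (nv > 1e-8) return(v / nv)
  }
}

# unit vectors making an angle in [theta_min, theta_max] (degrees) with the
# previous *bond* direction `prev`; i.e. the C-alpha pseudo-bond angle
# pi - theta lies in the complementary range.
cone_directions <- function(prev, k, theta_min, theta_max) {
  # orthonormal frame around prev
  a <- if (abs(prev[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- a - sum(a * prev) * prev
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(prev[2] * e1[3] - prev[3] * e1[2],
          prev[3] * e1[1] - prev[1] * e1[3],
          prev[1] * e1[2] - prev[2] * e1[1])
  # bend angle relative to continuing straight
  bend <- pi - stats::runif(k, theta_min, theta_max) * pi / 180
  phi <- stats::runif(k, 0, 2 * pi)
  t(vapply(seq_len(k), function(i) {
    cos(bend[i]) * prev +
      sin(bend[i]) * (cos(phi[i]) * e1 + sin(phi[i]) * e2)
  }, numeric(3)))
}

grow_segment <- function(coords, n_add, compactness, bond_length,
                         min_separation, theta_min, theta_max,
                         n_candidates = 24L, max_tries = 60L,
                         target = NULL) {
  for (step in seq_len(n_add)) {
    n <- nrow(coords)
    prev <- coords[n, ] - coords[n - 1L, ]
    prev <- prev / sqrt(sum(prev^2))
    centre <- if (is.null(target)) colMeans(coords) else target
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      dirs <- cone_directions(prev, n_candidates, theta_min, theta_max)
      cand <- sweep(dirs * bond_length, 2L, coords[n, ], "+")
      # excluded volume against all non-consecutive residues
      ok <- vapply(seq_len(nrow(cand)), function(i) {
        d2 <- rowSums(sweep(coords[seq_len(n - 1L), , drop = FALSE],
                            2L, cand[i, ], "-")^2)
        all(d2 >= min_separation^2)
      }, logical(1))
      if (!any(ok)) next
      cand <- cand[ok, , drop = FALSE]
      if (stats::runif(1) < compactness) {
        d2c <- rowSums(sweep(cand, 2L, centre, "-")^2)
        pick <- which.min(d2c)
      } else {
        pick <- sample.int(nrow(cand), 1L)
      }
      coords <- rbind(coords, cand[pick, ])
      placed <- TRUE
      break
    }
    if (!placed) return(NULL)
  }
  coords
}

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Generate a synthetic protein-like C-alpha trace
#'
#' Grows a self-avoiding walk with fixed consecutive C-alpha spacing (3.8
#' Angstrom by default), pseudo-bond angles sampled in a protein-like range
#' and an excluded-volume constraint between non-consecutive residues.
#' `compactness` biases each step toward the running centroid, so the
#' expected radius of gyration decreases monotonically as it approaches 1;
#' the low end yields elongated chains similar to the non-globular tail seen
#' in real decoy sets.  The elastic network at the given cutoff is verified
#' to be connected (the bonded backbone guarantees this whenever
#' `cutoff > bond_length`).
#'
#' @param n residue count (>= 4).
#' @param compactness real in \[0, 1\]: probability that a growth step picks
#'   the candidate direction closest to the running centroid.
#' @param gly_fraction expected fraction of glycines in the sequence.
#' @param seed integer seed; the output is a deterministic function of it.
#' @param bond_length consecutive C-alpha distance, Angstrom.
#' @param min_separation minimum distance between non-consecutive residues,
#'   Angstrom (excluded volume).
#' @param cutoff elastic-network cutoff used for the connectivity check,
#'   Angstrom.
#' @param theta_range pseudo-bond angle range in degrees.
#' @param max_restarts number of full restarts before giving up.
#' @param source_id label for the generated chain.
#' @return a [chain_structure()].
#' @export
generate_synthetic_chain <- function(n, compactness = 0.5,
                                     gly_fraction = 0.08, seed = NULL,
                                     bond_length = 3.8, min_separation = 4.0,
                                     cutoff = 7.5,
                                     theta_range = c(80, 150),
                                     max_restarts = 50L,
                                     source_id = NULL) {
  stopifnot(n >= 4L, compactness >= 0, compactness <= 1)
  if (is.null(source_id))
    source_id <- sprintf("synth_n%d_c%03d_s%s", n, round(100 * compactness),
                         if (is.null(seed)) "r" else seed)
  with_seed(seed, {
    for (attempt in seq_len(max_restarts)) {
      start <- rbind(c(0, 0, 0), random_unit_vector() * bond_length)
      coords <- grow_segment(start, n - 2L, compactness, bond_length,
                             min_separation, theta_range[1], theta_range[2])
      if (!is.null(coords)) {
        nm <- ifelse(stats::runif(n) < gly_fraction, "GLY", "ALA")
        ch <- chain_structure(coords, residue_names = nm,
                              source_id = source_id)
        if (network_is_connected(ch$coords, cutoff)) return(ch)
      }
    }
    stop("could not grow a self-avoiding chain of length ", n,
         " after ", max_restarts, " restarts")
  })
}

#' Generate a synthetic two-domain dumbbell chain
#'
#' Builds two compact globular domains joined by a near-straight linker: the
#' canonical geometry in which the lowest-energy fluctuation mode is a hinge
#' motion about the linker.  The sequence centre falls inside the linker, so
#' the default [hinge_centre()] points at the mechanical hinge.  This is a
#' synthetic stand-in for real two-domain proteins.
#'
#' @param n_domain residues per domain.
#' @param n_linker residues in the linker (total length is
#'   `2 * n_domain + n_linker`).
#' @param domain_compactness compactness of each domain walk (see
#'   [generate_synthetic_chain()]).
#' @param linker_theta pseudo-bond angle range (degrees) of the linker
#'   walk (near-straight by default).
#' @param seed integer seed.
#' @inheritParams generate_synthetic_chain
#' @return a [chain_structure()].
#' @details The linker is deliberately short: the two domains end up nearly
#'   in contact through a small interface, which is what keeps the elastic
#'   network mechanically rigid (exactly 6 zero modes) while leaving the
#'   inter-domain hinge mode much softer than any mode of a globular chain
#'   of the same size.  A long single-strand tether cannot transmit
#'   stiffness across a 7.5 Angstrom cutoff network and would produce
#'   spurious near-zero bending/torsion modes that real two-domain proteins
#'   do not have.
#' @export
generate_dumbbell_chain <- function(n_domain = 58L, n_linker = 4L,
                                    domain_compactness = 0.85,
                                    linker_theta = c(150, 175), seed = NULL,
                                    bond_length = 3.8, min_separation = 4.0,
                                    cutoff = 7.5, gly_fraction = 0.08,
                                    max_restarts = 50L, source_id = NULL) {
  stopifnot(n_domain >= 10L, n_linker >= 4L)
  n <- 2L * n_domain + n_linker
  if (is.null(source_id))
    source_id <- sprintf("dumbbell_n%d_s%s", n,
                         if (is.null(seed)) "r" else seed)
  with_seed(seed, {
    for (attempt in seq_len(max_restarts)) {
      start <- rbind(c(0, 0, 0), random_unit_vector() * bond_length)
      coords <- grow_segment(start, n_domain - 2L, domain_compactness,
                             bond_length, min_separation, 80, 150)
      if (is.null(coords)) next
      # linker: extended zigzag heading away from the first domain
      away <- coords[nrow(coords), ] - colMeans(coords)
      away <- colMeans(coords) + away * 1e3   # far target => outward bias
      coords <- grow_segment(coords, n_linker, 1.0, bond_length,
                             min_separation, linker_theta[1],
                             linker_theta[2], target = away)
      if (is.null(coords)) next
      # second domain: compact around the linker end
      coords <- grow_segment(coords, n_domain, domain_compactness,
                             bond_length, min_separation, 80, 150,
                             target = coords[nrow(coords), ])
      if (is.null(coords)) next
      nm <- ifelse(stats::runif(n) < gly_fraction, "GLY", "ALA")
      ch <- chain_structure(coords, residue_names = nm,
                            source_id = source_id)
      if (network_is_connected(ch$coords, cutoff)) return(ch)
    }
    stop("could not grow a dumbbell chain after ", max_restarts, " restarts")
  })
}

network_is_connected <- function(coords, cutoff) {
  n <- nrow(coords)
  d <- as.matrix(stats::dist(coords)) < cutoff
  # consecutive residues are always bonded
  d[cbind(seq_len(n - 1L), seq_len(n - 1L) + 1L)] <- TRUE
  d[cbind(seq_len(n - 1L) + 1L, seq_len(n - 1L))] <- TRUE
  seen <- logical(n); seen[1] <- TRUE; frontier <- 1L
  while (length(frontier)) {
    nb <- which(colSums(d[frontier, , drop = FALSE]) > 0 & !seen)
    seen[nb] <- TRUE
    frontier <- nb
  }
  all(seen)
}

#' Cut fixed-length decoys from a longer chain by window sliding
#'
#' A chain of length `100 + N` yields `N + 1` windows of length 100 (offsets
#' 0..N, half-open intervals).  Windows that span a chain break are dropped
#' with a warning (or raise an error).
#'
#' @param chain a [chain_structure()].
#' @param window window length (the surrogate's input size, default 100).
#' @param on_break `"drop"` (default) to exclude windows containing a break,
#'   `"error"` to fail.
#' @return list of [chain_structure()] decoys with `window_offset` set.
#' @export
make_decoys <- function(chain, window = 100L, on_break = c("drop", "error")) {
  on_break <- match.arg(on_break)
  n <- length(chain)
  if (n < window)
    stop("chain of length ", n, " is shorter than the window (", window, ")")
  breaks <- chain_break_positions(chain)
  offsets <- 0:(n - window)
  if (length(breaks)) {
    # window [k, k + window) contains break between residues b and b+1
    # (1-based b) iff k + 1 <= b <= k + window - 1
    bad <- vapply(offsets, function(k)
      any(breaks >= k + 1L & breaks <= k + window - 1L), logical(1))
    if (any(bad)) {
      if (on_break == "error")
        stop("chain break inside ", sum(bad), " window(s) of '",
             chain$source_id, "'")
      warning(sum(bad), " window(s) of '", chain$source_id,
              "' span a chain break and were dropped")
      offsets <- offsets[!bad]
    }
  }
  lapply(offsets, function(k) {
    idx <- (k + 1L):(k + window)
    chain_structure(chain$coords[idx, , drop = FALSE],
                    residue_names = chain$residue_names[idx],
                    source_id = chain$source_id,
                    orientation = chain$orientation,
                    window_offset = k)
  })
}

#' Reverse the sequence orientation of a chain
#'
#' The beta-Gaussian spectrum is invariant under sequence reversal, which is
#' what makes reversed copies a free data augmentation: same target, distinct
#' descriptor.
#'
#' @param chain a [chain_structure()].
#' @return the chain with coordinates and residue names reversed and the
#'   orientation flag toggled.
#' @export
reverse_chain <- function(chain) {
  n <- length(chain)
  chain_structure(chain$coords[n:1, , drop = FALSE],
                  residue_names = chain$residue_names[n:1],
                  source_id = chain$source_id,
                  orientation = if (chain$orientation == "direct")
                    "reversed" else "direct",
                  window_offset = chain$window_offset)
}

#' Radius of gyration of a chain
#'
#' Rg = sqrt(mean of squared distances from the centroid), the standard
#' globularity proxy.
#'
#' @param chain a [chain_structure()] or a coordinate matrix.
#' @return list with `radius_of_gyration` (Angstrom) and `n_residues`.
#' @export
radius_of_gyration <- function(chain) {
  xy <- if (inherits(chain, "chain_structure")) chain$coords
        else as.matrix(chain)
  n <- nrow(xy)
  ctr <- colMeans(xy)
  rg <- sqrt(sum(sweep(xy, 2L, ctr, "-")^2) / n)
  list(radius_of_gyration = rg, n_residues = n)
}

#' Write / read a chain as a plain tabular text file
#'
#' One row per residue: 0-based index, residue name, x, y, z.  Orientation,
#' source id and window offset travel in `# key: value` header lines.
#'
#' @param chain a [chain_structure()].
#' @param path output file.
#' @return `write_chain_tsv` returns `path` invisibly; `read_chain_tsv`
#'   returns a [chain_structure()].
#' @export
write_chain_tsv <- function(chain, path) {
  hdr <- c(paste0("# source_id: ", chain$source_id),
           paste0("# orientation: ", chain$orientation),
           paste0("# window_offset: ",
                  ifelse(is.na(chain$window_offset), "NA",
                         chain$window_offset)))
  body <- sprintf("%d\t%s\t%.6f\t%.6f\t%.6f",
                  seq_len(length(chain)) - 1L, chain$residue_names,
                  chain$coords[, 1], chain$coords[, 2], chain$coords[, 3])
  writeLines(c(hdr, "index\tresidue\tx\ty\tz", body), path)
  invisible(path)
}

#' @rdname write_chain_tsv
#' @export
read_chain_tsv <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  getv <- function(key) {
    m <- hdr[startsWith(hdr, paste0("# ", key, ":"))]
    if (!length(m)) return(NA_character_)
    trimws(sub(paste0("# ", key, ":"), "", m[1], fixed = TRUE))
  }
  tab <- utils::read.delim(text = lines[!startsWith(lines, "#")])
  wo <- getv("window_offset")
  chain_structure(as.matrix(tab[, c("x", "y", "z")]),
                  residue_names = tab$residue,
                  source_id = getv("source_id"),
                  orientation = getv("orientation"),
                  window_offset = if (wo == "NA") NA_integer_
                                  else as.integer(wo))
}
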
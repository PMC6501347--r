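test_that("pair energy matches closed forms and the cutoff rule", {
  p <- enm_params()
  two_ref <- matrix(c(0, 0, 0, 3, 0, 0), 2, 3, byrow = TRUE)
  expect_equal(pair_energy_total(two_ref, two_ref, p), 0)
  two_disp <- matrix(c(0, 0, 0, 4, 0, 0), 2, 3, byrow = TRUE)
  expect_equal(pair_energy_total(two_disp, two_ref, p), 0.5)
  far_ref <- matrix(c(0, 0, 0, 9, 0, 0), 2, 3, byrow = TRUE)
  far_disp <- matrix(c(0, 0, 0, 14, 2, 1), 2, 3, byrow = TRUE)
  expect_equal(pair_energy_total(far_disp, far_ref, p), 0)
  expect_error(pair_energy_total(two_ref, far_disp[1, , drop = FALSE], p),
               "shape")
})

test_that("ANM Hessian has the closed-form pair block and zero row sums", {
  two <- matrix(c(0, 0, 0, 3, 0, 0), 2, 3, byrow = TRUE)
  H <- build_anm_hessian(two)$matrix
  expect_equal(H[1:3, 4:6], diag(c(-1, 0, 0)))
  expect_equal(H[1:3, 1:3], diag(c(1, 0, 0)))
  ch <- fx_chain60()
  Hc <- build_anm_hessian(ch)$matrix
  expect_equal(max(abs(Hc - t(Hc))), 0)
  # translation invariance: applying the Hessian to a uniform translation
  # gives zero (3-vector-level row sums)
  for (mu in 1:3) {
    tr <- rep(0, ncol(Hc)); tr[seq(mu, ncol(Hc), by = 3)] <- 1
    expect_lt(max(abs(Hc %*% tr)), 1e-10)
  }
})

test_that("ANM Hessian matches the finite-difference energy oracle", {
  ch <- generate_synthetic_chain(5, compactness = 0.6, seed = 51)
  p <- enm_params()
  H <- build_anm_hessian(ch, p)$matrix
  Hfd <- fd_hessian(function(x) pair_energy_total(x, ch$coords, p),
                    ch$coords)
  expect_lt(max(abs(H - Hfd)), 1e-6)
})

test_that("C-beta placement follows the local-plane rule", {
  coords <- matrix(c(0, 0, 0, 3.8, 0, 0, 3.8, 3.8, 0, 7.6, 3.8, 0), 4, 3,
                   byrow = TRUE)
  ch <- chain_structure(coords, c("ALA", "ALA", "GLY", "ALA"))
  pl <- place_cbeta(ch, enm_params(cbeta_offset = 3.0))
  # terminals and the glycine carry no centroid
  expect_true(all(is.na(pl$positions[c(1, 3, 4), ])))
  # right-angle closed form at residue 2
  expect_equal(pl$positions[2, ],
               c(3.8, 0, 0) + 3.0 * c(1, -1, 0) / sqrt(2))
  # collinear trace: centroid omitted with a warning
  lin <- chain_structure(cbind(3.8 * (0:3), 0, 0), rep("ALA", 4))
  expect_warning(pl2 <- place_cbeta(lin), "collinear")
  expect_true(all(is.na(pl2$positions)))
})

test_that("C-beta jacobians match finite differences of the placement map", {
  ch <- generate_synthetic_chain(5, compactness = 0.6, seed = 52)
  p <- enm_params()
  pl <- place_cbeta(ch, p)
  h <- 1e-6
  for (i in which(!is.na(pl$positions[, 1]))) {
    J <- pl$jacobians[[i]]
    for (col in 1:9) {
      parent <- i - 1L + (col - 1L) %/% 3L
      mu <- (col - 1L) %% 3L + 1L
      up <- ch$coords; up[parent, mu] <- up[parent, mu] + h
      dn <- ch$coords; dn[parent, mu] <- dn[parent, mu] - h
      place_at <- function(x) {
        v <- 2 * x[i, ] - x[i - 1L, ] - x[i + 1L, ]
        x[i, ] + p$cbeta_offset * v / sqrt(sum(v^2))
      }
      expect_lt(max(abs((place_at(up) - place_at(dn)) / (2 * h) - J[, col])),
                1e-6)
    }
  }
})

test_that("beta-GM Hessian reduces to the C-alpha ANM when beta springs vanish", {
  ch <- fx_chain60()
  p0 <- enm_params(k_alpha_beta = 0, k_beta_beta = 0)
  Hb <- build_betagm_hessian(ch, p0)$matrix
  Ha <- build_anm_hessian(ch, p0)$matrix
  expect_equal(Hb, Ha, tolerance = 1e-12)
})

test_that("beta-GM Hessian is symmetric with zero row sums", {
  ch <- fx_chain60()
  H <- build_betagm_hessian(ch)$matrix
  expect_lt(max(abs(H - t(H))), 1e-10)
  for (mu in 1:3) {
    tr <- rep(0, ncol(H)); tr[seq(mu, ncol(H), by = 3)] <- 1
    expect_lt(max(abs(H %*% tr)), 1e-9)
  }
})

test_that("beta-GM Hessian matches the composed-energy oracle", {
  ch <- generate_synthetic_chain(6, compactness = 0.6, seed = 53)
  p <- enm_params()
  H <- build_betagm_hessian(ch, p)$matrix
  Hfd <- fd_hessian(function(x) betagm_energy(ch, x, p), ch$coords)
  expect_lt(max(abs(H - Hfd)), 1e-5)
})

test_that("spectrum: dimer closed form with 5 rigid modes", {
  two <- matrix(c(0, 0, 0, 3, 0, 0), 2, 3, byrow = TRUE)
  H <- build_anm_hessian(two, enm_params(k_alpha_alpha = 1))
  expect_warning(sp <- enm_spectrum(H, n_modes = 1), "5")
  expect_equal(sp$zero_mode_count, 5L)
  expect_equal(sp$eigenvalues, 2)
  # linearity in k: scaling all springs scales the eigenvalue
  H3 <- build_anm_hessian(two, enm_params(k_alpha_alpha = 3))
  expect_equal(suppressWarnings(enm_spectrum(H3, 1))$eigenvalues, 6)
  expect_error(suppressWarnings(enm_spectrum(H, n_modes = 2)),
               "non-zero eigenvalues")
})

test_that("spectrum has 6 zero modes and is rigid-motion invariant", {
  ch <- fx_chain60()
  sp <- enm_spectrum(ch)
  expect_equal(sp$zero_mode_count, 6L)
  expect_length(sp$eigenvalues, 10L)
  expect_true(all(sp$eigenvalues > 0))
  expect_true(all(diff(sp$eigenvalues) >= 0))
  R <- random_rotation(7)
  moved <- chain_structure(ch$coords %*% R +
                             matrix(c(10, -4, 2), length(ch), 3,
                                    byrow = TRUE),
                           ch$residue_names)
  sp2 <- enm_spectrum(moved)
  expect_lt(max(abs(sp2$eigenvalues - sp$eigenvalues) / sp$eigenvalues),
            1e-8)
})

test_that("beta-GM spectrum is invariant under sequence reversal", {
  ch <- fx_chain60()
  sp <- enm_spectrum(ch)
  spr <- enm_spectrum(reverse_chain(ch))
  expect_lt(max(abs(spr$eigenvalues - sp$eigenvalues) / sp$eigenvalues),
            1e-8)
})

test_that("eigenvalues scale linearly in the spring constants", {
  ch <- generate_synthetic_chain(40, 0.7, seed = 54)
  sp1 <- enm_spectrum(ch, params = enm_params())
  sp2 <- enm_spectrum(ch, params = enm_params(k_alpha_alpha = 2.5,
                                              k_alpha_beta = 2.5,
                                              k_beta_beta = 2.5,
                                              k_backbone = 2.5))
  expect_equal(sp2$eigenvalues, 2.5 * sp1$eigenvalues, tolerance = 1e-10)
})
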
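test_that("read_calpha_trace parses ATOM records, altlocs and glycines", {
  coords <- matrix(c(0, 0, 0,  3.8, 0, 0,  7.6, 0, 0,  7.6, 3.8, 0,
                     7.6, 3.8, 3.8), ncol = 3, byrow = TRUE)
  res <- c("MET", "ALA", "GLY", "LEU", "LYS")
  lines <- make_pdb_lines(coords, res)
  ch <- read_calpha_trace(paste(lines, collapse = "\n"))
  expect_s3_class(ch, "chain_structure")
  expect_equal(ch$coords, coords, tolerance = 1e-6)
  expect_equal(ch$residue_names, res)
  expect_equal(ch$residue_names[3], "GLY")

  # altloc B duplicate of residue 2 is ignored (altloc A kept)
  dup <- make_pdb_lines(coords[2, , drop = FALSE] + 5, res[2],
                        altloc = "B", serial_start = 99L, resseq_start = 2L)
  lines_b <- append(lines, dup, after = 2L)
  ch_b <- read_calpha_trace(paste(lines_b, collapse = "\n"))
  expect_equal(ch_b$coords, coords, tolerance = 1e-6)

  # non-CA atoms and HETATM records are ignored
  extra <- c(sub(" CA ", " CB ", lines[1]),
             sub("^ATOM  ", "HETATM", lines[1]))
  ch_c <- read_calpha_trace(paste(c(lines, extra), collapse = "\n"))
  expect_equal(nrow(ch_c$coords), 5L)

  # only the first MODEL is read
  two_models <- c("MODEL     1", lines, "ENDMDL", "MODEL     2",
                  make_pdb_lines(coords + 10, res), "ENDMDL")
  ch_m <- read_calpha_trace(paste(two_models, collapse = "\n"))
  expect_equal(ch_m$coords, coords, tolerance = 1e-6)
})

test_that("read_calpha_trace errors name chains and residues", {
  coords <- matrix(rnorm(15), 5, 3)
  lines <- make_pdb_lines(coords, rep("ALA", 5), chain = "B")
  expect_error(read_calpha_trace(paste(lines, collapse = "\n"), "A"),
               "available chains: B")
  # residue 3 present only through a non-CA atom
  lines2 <- lines
  lines2[3] <- sub(" CA ", " CB ", lines2[3])
  expect_error(read_calpha_trace(paste(lines2, collapse = "\n"), "B"),
               "without a CA")
  expect_error(
    read_calpha_trace(paste(lines[1:3], collapse = "\n"), "B"),
    "at least 4")
})

test_that("synthetic chains are deterministic, self-avoiding and bonded", {
  c1 <- generate_synthetic_chain(50, compactness = 0.7, seed = 1)
  c2 <- generate_synthetic_chain(50, compactness = 0.7, seed = 1)
  expect_identical(c1$coords, c2$coords)
  expect_identical(c1$residue_names, c2$residue_names)

  for (ch in list(c1, generate_synthetic_chain(50, 0.2, seed = 2))) {
    d <- sqrt(rowSums(diff(ch$coords)^2))
    expect_true(all(abs(d - 3.8) < 1e-9))
    dm <- as.matrix(dist(ch$coords))
    nonconsec <- abs(row(dm) - col(dm)) > 1
    expect_true(all(dm[nonconsec & upper.tri(dm)] >= 4.0 - 1e-9))
    expect_true(enmspec:::network_is_connected(ch$coords, 7.5))
  }
})

test_that("compactness monotonically shrinks the radius of gyration", {
  rg <- function(cmp) mean(vapply(1:10, function(i)
    radius_of_gyration(generate_synthetic_chain(80, cmp,
                                                seed = 5000 + i))$radius_of_gyration,
    numeric(1)))
  expect_lt(rg(0.9), rg(0.2))
})

test_that("dumbbell generator yields two lobes joined near the sequence centre", {
  db <- fx_dumbbell()
  expect_length(db, 120L)
  n <- length(db)
  # domain cores (away from the interface) are two distinct lobes
  dom1 <- colMeans(db$coords[1:40, ])
  dom2 <- colMeans(db$coords[(n - 39):n, ])
  expect_gt(sqrt(sum((dom1 - dom2)^2)), 20)
  # the default hinge centre lies in the linker: closer to the linker
  # midpoint than to either domain core
  centre <- hinge_centre(db)
  linker_mid <- colMeans(db$coords[59:62, ])   # linker = residues 59..62
  expect_lt(sqrt(sum((centre - linker_mid)^2)),
            min(sqrt(sum((centre - dom1)^2)), sqrt(sum((centre - dom2)^2))))
  # a soft hinge mode: lowest eigenvalue well below a globular chain's
  expect_lt(enm_spectrum(db)$eigenvalues[1],
            0.2 * enm_spectrum(fx_globular120())$eigenvalues[1])
})

test_that("make_decoys obeys the N - window + 1 count law", {
  ch105 <- generate_synthetic_chain(105, 0.8, seed = 11)
  dec <- make_decoys(ch105, window = 100)
  expect_length(dec, 6L)
  expect_equal(vapply(dec, `[[`, integer(1), "window_offset"), 0:5)
  expect_true(all(vapply(dec, length, integer(1)) == 100L))
  # decoy k holds residues [k, k + window)
  expect_equal(dec[[3]]$coords, ch105$coords[3:102, ])
  expect_equal(dec[[3]]$residue_names, ch105$residue_names[3:102])

  ch100 <- generate_synthetic_chain(100, 0.8, seed = 12)
  one <- make_decoys(ch100, window = 100)
  expect_length(one, 1L)
  expect_equal(one[[1]]$coords, ch100$coords)

  ch103 <- generate_synthetic_chain(103, 0.8, seed = 13)
  expect_equal(vapply(make_decoys(ch103, 100), `[[`, integer(1),
                      "window_offset"), 0:3)
  expect_error(make_decoys(ch100, window = 120), "shorter than the window")

  # property: count law over several lengths
  for (n in c(101, 104, 108)) {
    ch <- generate_synthetic_chain(n, 0.8, seed = n)
    expect_length(make_decoys(ch, 100), n - 100L + 1L)
  }
})

test_that("windows spanning a chain break are dropped", {
  ch <- generate_synthetic_chain(105, 0.8, seed = 21)
  broken <- ch
  broken$coords[53:105, ] <- broken$coords[53:105, ] + 60  # gap after 52
  expect_warning(dec <- make_decoys(broken, window = 50), "chain break")
  offs <- vapply(dec, `[[`, integer(1), "window_offset")
  # break between residues 52 and 53 excludes offsets 3..51 (0-based)
  expect_true(all(offs <= 2L | offs >= 52L))
  expect_error(make_decoys(broken, window = 50, on_break = "error"),
               "chain break")
})

test_that("reverse_chain is an involution preserving geometry", {
  ch <- fx_chain60()
  rev1 <- reverse_chain(ch)
  expect_equal(rev1$orientation, "reversed")
  expect_equal(rev1$coords[1, ], ch$coords[60, ])
  expect_equal(rev1$residue_names, rev(ch$residue_names))
  expect_identical(reverse_chain(rev1)$coords, ch$coords)
  expect_equal(radius_of_gyration(rev1)$radius_of_gyration,
               radius_of_gyration(ch)$radius_of_gyration)
})

test_that("radius_of_gyration matches closed forms", {
  expect_equal(radius_of_gyration(matrix(c(1, 2, 3), 1))$radius_of_gyration,
               0)
  two <- matrix(c(0, 0, 0, 2, 0, 0), 2, 3, byrow = TRUE)
  expect_equal(radius_of_gyration(two)$radius_of_gyration, 1.0)
  four <- matrix(c(0.5, 0.5, 0, 0.5, -0.5, 0, -0.5, 0.5, 0, -0.5, -0.5, 0),
                 4, 3, byrow = TRUE)
  expect_equal(radius_of_gyration(four)$radius_of_gyration, sqrt(0.5))
  expect_equal(radius_of_gyration(four)$n_residues, 4L)
})

test_that("chain TSV round-trips", {
  ch <- make_decoys(generate_synthetic_chain(104, 0.7, seed = 31), 100)[[3]]
  path <- tempfile(fileext = ".tsv")
  write_chain_tsv(ch, path)
  back <- read_chain_tsv(path)
  expect_equal(back$coords, ch$coords, tolerance = 1e-6)
  expect_equal(back$residue_names, ch$residue_names)
  expect_equal(back$window_offset, ch$window_offset)
  expect_equal(back$orientation, ch$orientation)
})
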
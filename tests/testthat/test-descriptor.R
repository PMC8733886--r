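# Local frames, grid-mask construction, descriptor extraction.

test_that("local frame follows the stated sign convention", {
  fr <- build_local_frame(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0))
  expect_equal(fr$e_x, c(1, 0, 0))
  expect_equal(fr$e_y, c(0, 0, 1))
  expect_equal(fr$e_z, c(0, -1, 0))
  expect_equal(fr$origin, c(1, 0, 0))
})

test_that("frames are orthonormal, right-handed and rotation-equivariant", {
  set.seed(10)
  for (i in 1:200) {
    n <- rnorm(3); ca <- n + rnorm(3); cc <- ca + rnorm(3)
    d_nca <- sqrt(sum((ca - n)^2))
    cr <- mapseqid:::cross3(ca - n, cc - ca)
    if (d_nca < 0.5 || sqrt(sum(cr^2)) < 1e-6) next
    fr <- build_local_frame(n, ca, cc)
    B <- cbind(fr$e_x, fr$e_y, fr$e_z)
    expect_equal(crossprod(B), diag(3), tolerance = 1e-9)
    expect_equal(mapseqid:::cross3(fr$e_x, fr$e_y), fr$e_z, tolerance = 1e-12)
    R <- mapseqid:::random_rotation()
    fr2 <- build_local_frame(R %*% n, R %*% ca, R %*% cc)
    expect_equal(fr2$e_x, as.vector(R %*% fr$e_x), tolerance = 1e-9)
    expect_equal(fr2$e_y, as.vector(R %*% fr$e_y), tolerance = 1e-9)
  }
  expect_error(build_local_frame(c(0, 0, 0), c(0, 0, 0), c(1, 1, 0)),
               class = "degenerate_geometry")
  expect_error(build_local_frame(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)),
               class = "degenerate_geometry")
})

test_that("grid mask equals brute-force lattice membership", {
  lib1 <- data.frame(restype = "A", rotamer = 0L, atom = "CB", element = "C",
                     x = 1.5, y = 0.8, z = 0.0)
  mask <- build_grid_mask(lib1, spacing = 1, inclusion_radius = 1)
  expect_equal(mask$n_points, 4)
  expect_equal(mask$offsets,
               matrix(as.integer(c(1, 0, 0,
                                   1, 1, 0,
                                   2, 0, 0,
                                   2, 1, 0)), ncol = 3, byrow = TRUE),
               ignore_attr = TRUE)
  # radius 0 with an atom exactly on a lattice point keeps only that point
  lib0 <- data.frame(restype = "A", rotamer = 0L, atom = "CB", element = "C",
                     x = 2, y = -1, z = 3)
  m0 <- build_grid_mask(lib0, spacing = 1, inclusion_radius = 0)
  expect_equal(m0$offsets, matrix(c(2L, -1L, 3L), 1), ignore_attr = TRUE)
  # duplicating the library leaves the mask unchanged
  lib <- shared_library()
  m1 <- shared_mask()
  m2 <- build_grid_mask(rbind(lib, lib))
  expect_identical(m1$offsets, m2$offsets)
  # brute-force check on a random sub-library
  set.seed(11)
  sub <- lib[sample(nrow(lib), 25), ]
  mk <- build_grid_mask(sub, spacing = 1, inclusion_radius = 1)
  at <- as.matrix(sub[, c("x", "y", "z")])
  lo <- floor(apply(at, 2, min) - 1); hi <- ceiling(apply(at, 2, max) + 1)
  brute <- list()
  for (i in lo[1]:hi[1]) for (j in lo[2]:hi[2]) for (k in lo[3]:hi[3]) {
    d <- sqrt(min(colSums((t(at) - c(i, j, k))^2)))
    if (d <= 1) brute[[length(brute) + 1L]] <- c(i, j, k)
  }
  brute <- do.call(rbind, brute)
  brute <- brute[order(brute[, 1], brute[, 2], brute[, 3]), ]
  expect_equal(mk$offsets, brute, ignore_attr = TRUE)
})

test_that("bundled library yields the frozen canonical mask", {
  mask <- shared_mask()
  expect_equal(mask$n_points, 244)
  expect_gt(mask$n_points, 100)   # "low hundreds" for a 20-type library
  expect_lt(mask$n_points, 500)
  expect_false(any(duplicated(mask$offsets)))
})

test_that("descriptors: constant map, length contract, out-of-map flagging", {
  mask <- shared_mask()
  m <- density_map(array(7, c(40, 40, 40)), 1, origin = c(-20, -20, -20))
  fr <- build_local_frame(c(-1.4, 0, 0), c(0, 0, 0), c(0.5, 1.3, 0))
  d <- extract_descriptor(m, fr, mask, normalizer = list(mean = 7, sd = 2))
  expect_length(d, mask$n_points)
  expect_equal(d, rep(0, mask$n_points))
  # raw values without normalizer
  expect_equal(extract_descriptor(m, fr, mask), rep(7, mask$n_points))
  # frame near the map edge cannot be sampled -> flagged as NULL
  m_small <- density_map(array(7, c(8, 8, 8)), 1)
  fr_edge <- build_local_frame(c(-1.4, 0, 0) + 1, c(1, 1, 1), c(1.5, 2.3, 1))
  expect_null(extract_descriptor(m_small, fr_edge, mask))
  # toy 4-point mask gives length-4 descriptors
  lib1 <- data.frame(restype = "A", rotamer = 0L, atom = "CB", element = "C",
                     x = 1.5, y = 0.8, z = 0.0)
  mask4 <- build_grid_mask(lib1, 1, 1)
  expect_length(extract_descriptor(m, fr, mask4), 4)
})

test_that("register shift changes descriptors measurably", {
  set.seed(12)
  seqs <- paste(sample(aa_alphabet(), 20, TRUE), collapse = "")
  pep <- build_peptide(seqs, "helix")
  map <- simulate_map(pep$atoms, map_sim_params(box_margin = 10))
  mask <- shared_mask()
  bb <- as.matrix(pep$residues[, c("ca_x", "ca_y", "ca_z")])
  nm <- map_normalizer(map, bb)
  descs <- lapply(seq_len(20), function(i) {
    r <- pep$residues[i, ]
    fr <- build_local_frame(c(r$n_x, r$n_y, r$n_z), c(r$ca_x, r$ca_y, r$ca_z),
                            c(r$c_x, r$c_y, r$c_z))
    extract_descriptor(map, fr, mask, nm)
  })
  ok <- !vapply(descs, is.null, logical(1))
  idx <- which(ok)
  idx <- idx[(idx + 1) %in% which(ok)]
  cos_shift <- vapply(idx, function(i) {
    a <- descs[[i]]; b <- descs[[i + 1]]
    sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  }, numeric(1))
  expect_lt(mean(cos_shift), 0.99)
})
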
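# Gaussian-atom map simulation, peptide building, decoy databases.

test_that("simulated maps: peak position, mass integral, determinism", {
  params <- map_sim_params(voxel_size = 1, atom_width = 1, box_margin = 6)
  one <- data.frame(element = "C", x = 0, y = 0, z = 0)
  map <- simulate_map(one, params)
  # global maximum at the atom position
  peak <- which(map$values == max(map$values), arr.ind = TRUE)[1, ]
  peak_xyz <- map$origin + (peak - 1) * map$voxel_size
  expect_equal(as.numeric(peak_xyz), c(0, 0, 0), tolerance = 1e-9)
  # Gaussian mass: sum * voxel volume ~ w * (2 pi sigma^2)^(3/2)
  expect_equal(sum(map$values) * prod(map$voxel_size), 6 * (2 * pi)^1.5,
               tolerance = 0.01)
  # determinism under seed (with noise)
  pn <- map_sim_params(noise_sd = 0.3, seed = 9)
  m1 <- simulate_map(one, pn)
  m2 <- simulate_map(one, pn)
  expect_identical(m1$values, m2$values)
  pn2 <- map_sim_params(noise_sd = 0.3, seed = 10)
  expect_false(identical(simulate_map(one, pn2)$values, m1$values))
})

test_that("integer-voxel model shifts translate the noise-free map exactly", {
  set.seed(60)
  pep <- build_peptide("AWK", "helix")
  params <- map_sim_params(voxel_size = 1)
  m1 <- simulate_map(pep$atoms, params)
  at2 <- pep$atoms
  at2$x <- at2$x + 3; at2$y <- at2$y - 2; at2$z <- at2$z + 1
  m2 <- simulate_map(at2, params)
  expect_lt(max(abs(m2$values - m1$values)), 1e-6 * max(m1$values))
  expect_equal(m2$origin - m1$origin, c(3, -2, 1))
})

test_that("built peptides have ideal backbone geometry", {
  pep <- build_peptide("ACDEFGHIKL", "helix")
  r <- pep$residues
  d_nca <- sqrt((r$n_x - r$ca_x)^2 + (r$n_y - r$ca_y)^2 + (r$n_z - r$ca_z)^2)
  d_cac <- sqrt((r$c_x - r$ca_x)^2 + (r$c_y - r$ca_y)^2 + (r$c_z - r$ca_z)^2)
  expect_equal(d_nca, rep(1.458, 10), tolerance = 1e-6)
  expect_equal(d_cac, rep(1.525, 10), tolerance = 1e-6)
  i <- 1:9
  d_cn <- sqrt((r$c_x[i] - r$n_x[i + 1])^2 + (r$c_y[i] - r$n_y[i + 1])^2 +
               (r$c_z[i] - r$n_z[i + 1])^2)
  expect_equal(d_cn, rep(1.329, 9), tolerance = 1e-6)
  # helical pitch: CA(i) to CA(i+3) around 5-6 A
  ca <- as.matrix(r[, c("ca_x", "ca_y", "ca_z")])
  d13 <- sqrt(rowSums((ca[4:10, ] - ca[1:7, ])^2))
  expect_true(all(d13 > 4.5 & d13 < 6.5))
  # strands are extended: CA(i) to CA(i+2) > 6 A
  pep_s <- build_peptide("ACDEFGHIKL", "strand")
  ca_s <- as.matrix(pep_s$residues[, c("ca_x", "ca_y", "ca_z")])
  d2 <- sqrt(rowSums((ca_s[3:10, ] - ca_s[1:8, ])^2))
  expect_true(all(d2 > 6))
  expect_error(build_peptide("AB1"), class = "format_error")
})

test_that("glycine fixtures have no side-chain density", {
  paramsG <- map_sim_params(box_margin = 10, seed = 61)
  fixG <- build_residue_fixture("G", params = paramsG, context = 0L,
                                random_pose = FALSE)
  fixW <- build_residue_fixture("W", params = paramsG, context = 0L,
                                random_pose = FALSE)
  mask <- shared_mask()
  descf <- function(fix) {
    r <- fix$residue
    fr <- build_local_frame(c(r$n_x, r$n_y, r$n_z), c(r$ca_x, r$ca_y, r$ca_z),
                            c(r$c_x, r$c_y, r$c_z))
    # raw values; points far from backbone should be empty for glycine
    extract_descriptor(fix$map, fr, mask)
  }
  # distance of each mask point from the three backbone atoms
  r <- fixG$residue
  fr <- build_local_frame(c(r$n_x, r$n_y, r$n_z), c(r$ca_x, r$ca_y, r$ca_z),
                          c(r$c_x, r$c_y, r$c_z))
  R <- cbind(fr$e_x, fr$e_y, fr$e_z)
  pts <- sweep(mask$offsets %*% t(R) * mask$spacing, 2, fr$origin, "+")
  bb <- rbind(c(r$n_x, r$n_y, r$n_z), c(r$ca_x, r$ca_y, r$ca_z),
              c(r$c_x, r$c_y, r$c_z))
  # beyond 3.5 A the backbone Gaussians (sigma 1 A) have decayed to ~0.02
  dmin <- apply(pts, 1, function(p) sqrt(min(colSums((t(bb) - p)^2))))
  far <- dmin > 3.5
  expect_gt(sum(far), 50)
  dG <- descf(fixG)
  dW <- descf(fixW)
  expect_lt(max(dG[far]), 0.1)        # glycine: essentially zero out there
  expect_gt(max(dW[far]), 1)          # tryptophan: strong side-chain density
})

test_that("training sets are balanced, labelled and deterministic", {
  mask <- shared_mask()
  ts <- make_training_set(3, seed = 62, mask = mask, library = shared_library())
  expect_equal(dim(ts$x), c(60, mask$n_points))
  expect_equal(as.vector(table(ts$y)), rep(3, 20))
  expect_true(all(is.finite(ts$x)))
  ts2 <- make_training_set(3, seed = 62, mask = mask, library = shared_library())
  expect_identical(ts$x, ts2$x)
  ts3 <- make_training_set(3, seed = 63, mask = mask, library = shared_library())
  expect_false(identical(ts$x, ts3$x))
})

test_that("decoy databases respect size, lengths and composition", {
  db <- generate_decoy_db(1000, c(50, 500), seed = 64)
  expect_equal(nrow(db), 1000)
  lens <- nchar(db$seq)
  expect_true(all(lens >= 50 & lens <= 500))
  expect_false(anyDuplicated(db$id) > 0)
  # uniform composition at large letter counts
  letters_all <- unlist(strsplit(paste(db$seq, collapse = ""), ""))
  freq <- table(factor(letters_all, levels = aa_alphabet())) / length(letters_all)
  expect_true(all(abs(freq - 0.05) < 0.005))
  # planted target is retrievable verbatim
  db2 <- plant_target(db, "MKLVWAAA", id = "truth", seed = 65)
  expect_equal(nrow(db2), 1001)
  expect_equal(db2$seq[db2$id == "truth"], "MKLVWAAA")
})
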
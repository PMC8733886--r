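# Synthetic data generation: Gaussian-atom density maps computed from models,
# ideal peptide builders (helix/strand via internal-coordinate chain
# construction), balanced descriptor training sets, and decoy FASTA
# databases. Everything is deterministic under a seed so the whole pipeline
# can be trained and validated without any external data.

ELEMENT_WEIGHTS <- c(C = 6, N = 7, O = 8, S = 16)

#' Map-simulation parameters
#'
#' @param voxel_size Voxel edge in Angstrom (default 1.0).
#' @param atom_width Gaussian sigma per atom in Angstrom (default 1.0), a
#'   resolution surrogate: larger widths emulate lower-resolution maps.
#' @param noise_sd Gaussian noise level as a fraction of the signal standard
#'   deviation (default 0 = noise-free).
#' @param box_margin Padding around the model bounding box in Angstrom
#'   (default 5).
#' @param seed RNG seed for the noise.
#' @return List of class `map_sim_params`.
#' @export
map_sim_params <- function(voxel_size = 1.0, atom_width = 1.0, noise_sd = 0,
                           box_margin = 5, seed = 1L) {
  stopifnot(voxel_size > 0, atom_width > 0, noise_sd >= 0, box_margin >= 0)
  structure(list(voxel_size = voxel_size, atom_width = atom_width,
                 noise_sd = noise_sd, box_margin = box_margin,
                 seed = as.integer(seed)),
            class = "map_sim_params")
}

#' Simulate a Gaussian-atom density map from a model
#'
#' Each atom contributes `w_elem * exp(-r^2 / (2 sigma^2))` with weights
#' proportional to atomic number (C 6, N 7, O 8, S 16) on a grid covering
#' the model bounding box plus `box_margin`. Optional white noise with
#' standard deviation `noise_sd * sd(signal)` is added (seeded).
#'
#' @param atoms Data frame with columns `element`, `x`, `y`, `z`.
#' @param params A [map_sim_params].
#' @return A [density_map] (non-periodic).
#' @export
simulate_map <- function(atoms, params = map_sim_params()) {
  stopifnot(nrow(atoms) > 0)
  vx <- params$voxel_size
  sig <- params$atom_width
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  lo <- apply(xyz, 2, min) - params$box_margin
  hi <- apply(xyz, 2, max) + params$box_margin
  dims <- pmax(ceiling((hi - lo) / vx) + 1L, 2L)
  origin <- lo
  vals <- array(0, dim = dims)
  w <- ELEMENT_WEIGHTS[toupper(atoms$element)]
  w[is.na(w)] <- 6            # unknown elements counted as carbon
  # truncating each atom's Gaussian at 6 sigma keeps the omitted tail (and
  # any box-boundary sensitivity under model shifts) below ~1e-7 of the peak
  cutoff <- 6 * sig
  ax_x <- origin[1] + (seq_len(dims[1]) - 1) * vx
  ax_y <- origin[2] + (seq_len(dims[2]) - 1) * vx
  ax_z <- origin[3] + (seq_len(dims[3]) - 1) * vx
  for (a in seq_len(nrow(xyz))) {
    p <- xyz[a, ]
    ix <- which(abs(ax_x - p[1]) <= cutoff)
    iy <- which(abs(ax_y - p[2]) <= cutoff)
    iz <- which(abs(ax_z - p[3]) <= cutoff)
    if (!length(ix) || !length(iy) || !length(iz)) next
    gx <- exp(-(ax_x[ix] - p[1])^2 / (2 * sig^2))
    gy <- exp(-(ax_y[iy] - p[2])^2 / (2 * sig^2))
    gz <- exp(-(ax_z[iz] - p[3])^2 / (2 * sig^2))
    vals[ix, iy, iz] <- vals[ix, iy, iz] +
      w[a] * (gx %o% gy %o% gz)
  }
  if (params$noise_sd > 0) {
    set.seed(params$seed)
    vals <- vals + stats::rnorm(length(vals), 0,
                                params$noise_sd * stats::sd(vals))
  }
  density_map(vals, vx, origin, periodic = FALSE)
}

# Place atom D given A-B-C with bond |CD|, angle B-C-D (deg) and dihedral
# A-B-C-D (deg); the standard internal-coordinate (NeRF) construction.
place_atom <- function(a, b, c, bond, angle, dihedral) {
  ang <- angle * pi / 180
  dih <- dihedral * pi / 180
  bc <- unit3(c - b)
  n <- unit3(cross3(b - a, bc))
  m <- cross3(n, bc)
  d2 <- c(-bond * cos(ang), bond * sin(ang) * cos(dih), bond * sin(ang) * sin(dih))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

#' Build an ideal peptide with side chains
#'
#' Constructs an N/CA/C(/O) backbone by internal coordinates with fixed
#' (phi, psi) — alpha-helix (-57, -47) or beta-strand (-139, 135) — and hangs
#' frame-aligned library side chains off every residue. Used both as a model
#' input and as the atom list for [simulate_map].
#'
#' @param sequence One-letter amino-acid string.
#' @param conformation `"helix"` or `"strand"`.
#' @param library Side-chain library (default bundled); the conformer used
#'   per residue is `rotamer`.
#' @param rotamer Conformer id to use where available (default 0).
#' @param chain Chain identifier (default "A").
#' @return List: `residues` (backbone residue table, see
#'   [read_backbone_model]), `atoms` (data frame `element`, `x`, `y`, `z`
#'   with backbone and side-chain atoms).
#' @export
build_peptide <- function(sequence, conformation = c("helix", "strand"),
                          library = NULL, rotamer = 0L, chain = "A") {
  conformation <- match.arg(conformation)
  if (is.null(library)) library <- read_sidechain_library()
  letters1 <- strsplit(toupper(sequence), "")[[1]]
  if (!all(letters1 %in% AA))
    stop_classed(sprintf("unknown residue type(s): %s",
                         paste(setdiff(letters1, AA), collapse = ",")),
                 "format_error")
  n_res <- length(letters1)
  phi_psi <- if (conformation == "helix") c(-57, -47) else c(-139, 135)
  phi <- phi_psi[1]; psi <- phi_psi[2]
  N <- matrix(0, n_res, 3); CA <- matrix(0, n_res, 3); C <- matrix(0, n_res, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(1.458, 0, 0)
  ang <- 111.2 * pi / 180
  C[1, ] <- CA[1, ] + 1.525 * c(cos(pi - ang), sin(pi - ang), 0)
  for (i in seq_len(n_res - 1)) {
    N[i + 1, ] <- place_atom(N[i, ], CA[i, ], C[i, ], 1.329, 116.2, psi)
    CA[i + 1, ] <- place_atom(CA[i, ], C[i, ], N[i + 1, ], 1.458, 121.7, 180)
    C[i + 1, ] <- place_atom(C[i, ], N[i + 1, ], CA[i + 1, ], 1.525, 111.2, phi)
  }
  atoms <- list()
  for (i in seq_len(n_res)) {
    atoms[[length(atoms) + 1L]] <- data.frame(
      element = c("N", "C", "C"),
      x = c(N[i, 1], CA[i, 1], C[i, 1]),
      y = c(N[i, 2], CA[i, 2], C[i, 2]),
      z = c(N[i, 3], CA[i, 3], C[i, 3]), stringsAsFactors = FALSE)
    if (i < n_res) {   # carbonyl O anti to the next N
      O <- place_atom(N[i, ], CA[i, ], C[i, ], 1.231, 120.5, psi - 180)
      atoms[[length(atoms) + 1L]] <- data.frame(element = "O", x = O[1],
                                                y = O[2], z = O[3],
                                                stringsAsFactors = FALSE)
    }
    side <- library[library$restype == letters1[i] &
                      library$rotamer %in% c(rotamer, 0L), , drop = FALSE]
    if (nrow(side) > 0) {
      rot_use <- if (any(side$rotamer == rotamer)) rotamer else 0L
      side <- side[side$rotamer == rot_use, , drop = FALSE]
      fr <- build_local_frame(N[i, ], CA[i, ], C[i, ])
      R <- cbind(fr$e_x, fr$e_y, fr$e_z)
      glob <- t(R %*% t(as.matrix(side[, c("x", "y", "z")]))) +
        matrix(CA[i, ], nrow(side), 3, byrow = TRUE)
      atoms[[length(atoms) + 1L]] <- data.frame(element = side$element,
                                                x = glob[, 1], y = glob[, 2],
                                                z = glob[, 3],
                                                stringsAsFactors = FALSE)
    }
  }
  residues <- data.frame(chain = chain, resno = seq_len(n_res), ins = "",
                         restype = letters1,
                         n_x = N[, 1], n_y = N[, 2], n_z = N[, 3],
                         ca_x = CA[, 1], ca_y = CA[, 2], ca_z = CA[, 3],
                         c_x = C[, 1], c_y = C[, 2], c_z = C[, 3],
                         stringsAsFactors = FALSE)
  list(residues = residues, atoms = do.call(rbind, atoms))
}

#' Build a labelled-residue fixture in chain context (backbone + map)
#'
#' The labelled residue is placed at the centre of a short ideal peptide
#' (`2 * context + 1` residues) with randomly typed neighbours, so the
#' simulated density includes the backbone and side-chain context a residue
#' sees inside a real traced chain. The whole peptide is given a random
#' orientation and sub-voxel offset before map simulation.
#'
#' @param restype One-letter residue type of the central residue.
#' @param rotamer Conformer id for the central side chain (default 0).
#' @param params A [map_sim_params] (its `seed` seeds neighbours, pose and
#'   noise).
#' @param library Side-chain library (default bundled).
#' @param context Residues on each side of the labelled one (default 3).
#' @param conformation `"helix"` or `"strand"`.
#' @param random_pose Randomize orientation/offset (default TRUE).
#' @return List: `residue` (one-row residue table of the central residue),
#'   `residues` (full peptide backbone), `map` ([density_map]).
#' @export
build_residue_fixture <- function(restype, rotamer = 0L,
                                  params = map_sim_params(), library = NULL,
                                  context = 3L, conformation = "helix",
                                  random_pose = TRUE) {
  if (!restype %in% AA)
    stop_classed(sprintf("unknown residue type '%s'", restype), "format_error")
  if (is.null(library)) library <- read_sidechain_library()
  set.seed(params$seed)
  neighbours <- sample(AA, 2L * context, replace = TRUE)
  seqv <- c(neighbours[seq_len(context)], restype,
            neighbours[context + seq_len(context)])
  pep <- build_peptide(paste(seqv, collapse = ""), conformation,
                       library = library, rotamer = rotamer)
  atoms <- pep$atoms
  res_all <- pep$residues
  if (random_pose) {
    R <- random_rotation()
    shift <- stats::runif(3, 0, params$voxel_size)
    xyz <- as.matrix(atoms[, c("x", "y", "z")]) %*% t(R)
    atoms[, c("x", "y", "z")] <- sweep(xyz, 2, shift, "+")
    for (pre in c("n", "ca", "c")) {
      cols <- paste0(pre, "_", c("x", "y", "z"))
      res_all[, cols] <- sweep(as.matrix(res_all[, cols]) %*% t(R), 2, shift, "+")
    }
  }
  map <- simulate_map(atoms, params)
  list(residue = res_all[context + 1L, , drop = FALSE], residues = res_all,
       map = map)
}

#' Generate a balanced descriptor training set
#'
#' `n_per_type` single-residue fixtures per residue type (conformers cycled,
#' random orientations and sub-voxel offsets), maps simulated with `params`,
#' descriptors extracted with `mask` after per-map standardization.
#'
#' @param n_per_type Examples per residue type.
#' @param params A [map_sim_params]; per-example seeds are derived from
#'   `seed`.
#' @param seed Master seed.
#' @param mask Grid mask (default: built from `library`).
#' @param library Side-chain library (default bundled).
#' @return List: `x` (descriptor matrix), `y` (one-letter labels).
#' @export
make_training_set <- function(n_per_type, params = map_sim_params(),
                              seed = 1L, mask = NULL, library = NULL) {
  if (is.null(library)) library <- read_sidechain_library()
  if (is.null(mask)) mask <- build_grid_mask(library)
  # the simulated box must cover the whole mask even for small side chains
  mask_extent <- max(sqrt(rowSums((mask$offsets * mask$spacing)^2)))
  params$box_margin <- max(params$box_margin, mask_extent + 2 * params$voxel_size)
  rot_by_type <- lapply(AA, function(a) sort(unique(library$rotamer[library$restype == a])))
  names(rot_by_type) <- AA
  rot_by_type$G <- 0L     # glycine: empty side chain, descriptor learns emptiness
  n_total <- 20L * n_per_type
  x <- matrix(NA_real_, n_total, mask$n_points)
  y <- character(n_total)
  k <- 0L
  for (a in AA) {
    rots <- rot_by_type[[a]]
    if (length(rots) == 0) rots <- 0L
    for (i in seq_len(n_per_type)) {
      k <- k + 1L
      p_i <- params
      p_i$seed <- as.integer((as.numeric(seed) * 1000003 + k) %% 2147483629)
      fix <- build_residue_fixture(a, rotamer = rots[1L + (i - 1L) %% length(rots)],
                                   params = p_i, library = library,
                                   conformation = if (i %% 2 == 0) "strand" else "helix")
      r <- fix$residue
      fr <- build_local_frame(c(r$n_x, r$n_y, r$n_z), c(r$ca_x, r$ca_y, r$ca_z),
                              c(r$c_x, r$c_y, r$c_z))
      bb <- rbind(as.matrix(fix$residues[, c("n_x", "n_y", "n_z")]),
                  as.matrix(fix$residues[, c("ca_x", "ca_y", "ca_z")]),
                  as.matrix(fix$residues[, c("c_x", "c_y", "c_z")]))
      norm <- map_normalizer(fix$map, bb)
      d <- extract_descriptor(fix$map, fr, mask, norm)
      if (is.null(d))
        stop_classed("fixture descriptor fell outside its own map; increase box_margin",
                     "out_of_bounds")
      x[k, ] <- d
      y[k] <- a
    }
  }
  list(x = x, y = y)
}

#' Generate a decoy sequence database
#'
#' i.i.d. letters from `composition`, lengths uniform in `length_range`.
#'
#' @param n_sequences Number of decoys.
#' @param length_range Integer length range, e.g. `c(50, 500)`.
#' @param composition 20-vector of letter frequencies (default uniform).
#' @param seed RNG seed.
#' @param prefix Identifier prefix (default "decoy").
#' @return A `sequence_db`.
#' @export
generate_decoy_db <- function(n_sequences, length_range = c(50, 500),
                              composition = rep(1 / 20, 20), seed = 1L,
                              prefix = "decoy") {
  stopifnot(n_sequences >= 1, length(length_range) == 2,
            length_range[1] >= 1, length_range[2] >= length_range[1],
            length(composition) == 20)
  composition <- composition / sum(composition)
  set.seed(seed)
  lens <- sample(length_range[1]:length_range[2], n_sequences, replace = TRUE)
  seqs <- vapply(lens, function(L)
    paste(sample(AA, L, replace = TRUE, prob = composition), collapse = ""),
    character(1))
  sequence_db(sprintf("%s%05d", prefix, seq_len(n_sequences)), seqs)
}

#' Plant a true target sequence in a database
#'
#' Inserts `true_sequence` at a seeded random position in the entry order.
#'
#' @param db A `sequence_db`.
#' @param true_sequence Amino-acid string.
#' @param id Identifier for the planted entry (default "target").
#' @param seed RNG seed for the insertion position.
#' @return A `sequence_db` with one extra entry.
#' @export
plant_target <- function(db, true_sequence, id = "target", seed = 1L) {
  set.seed(seed)
  pos <- sample.int(nrow(db) + 1L, 1L)
  ids <- append(db$id, id, after = pos - 1L)
  seqs <- append(db$seq, toupper(true_sequence), after = pos - 1L)
  sequence_db(ids, seqs)
}

#' Simulate a complete fixture bundle on disk
#'
#' Writes a map (MRC), a main-chain-only model (PDB), the true sequence and a
#' decoy database with the planted target (FASTA) — a bundle consumable by
#' the identification and assignment front ends without edits.
#'
#' @param out_dir Output directory (created if missing).
#' @param seed Master seed.
#' @param n_residues Model length (default 80).
#' @param n_decoys Database decoys (default 1000).
#' @param params A [map_sim_params].
#' @param conformation Peptide conformation (default "helix").
#' @return Named list of the written paths plus the true sequence.
#' @export
simulate_bundle <- function(out_dir, seed = 1L, n_residues = 80L,
                            n_decoys = 1000L, params = map_sim_params(seed = seed),
                            conformation = "helix") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  true_seq <- paste(sample(AA, n_residues, replace = TRUE), collapse = "")
  pep <- build_peptide(true_seq, conformation)
  map <- simulate_map(pep$atoms, params)
  map_path <- file.path(out_dir, "map.mrc")
  model_path <- file.path(out_dir, "model.pdb")
  db_path <- file.path(out_dir, "db.fasta")
  write_density_map(map, map_path)
  res <- pep$residues
  res$restype <- NA_character_     # main-chain-only model: no sequence on disk
  frag <- structure(list(fragment_id = "sim", residues = res),
                    class = "chain_fragment")
  write_model_with_sequence(list(frag), list(NA), model_path, cb_stubs = FALSE)
  db <- generate_decoy_db(n_decoys, seed = seed + 1L)
  db <- plant_target(db, true_seq, id = "true_target", seed = seed + 2L)
  write_fasta(db, db_path)
  list(map = map_path, model = model_path, db = db_path,
       true_sequence = true_seq, target_id = "true_target")
}
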
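# Shared synthetic fixtures. Expensive artifacts (the bundled mask, the
# trained toy classifier) are built once per test session and memoized.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

shared_library <- function() memo("library", read_sidechain_library())

shared_mask <- function() memo("mask", build_grid_mask(shared_library()))

# Classifier trained on the standard synthetic corpus: 200 balanced examples
# per residue type, noise-free Gaussian-atom maps, 300 epochs (enough to
# resolve the hard single-atom contrasts N/D and Q/E).
toy_classifier <- function() memo("classifier", {
  mask <- shared_mask()
  ts <- make_training_set(200, seed = 11, mask = mask, library = shared_library())
  cfg <- classifier_config(input_dim = mask$n_points, epochs = 300, seed = 3)
  fit_residue_classifier(ts$x, ts$y, cfg, mask = mask, map_kind = "synthetic")
})

# Fresh evaluation set (seed disjoint from training); returns accuracy of the
# toy classifier on it.
eval_accuracy <- function(clf, n_per_type, params = map_sim_params(), seed = 999) {
  ev <- make_training_set(n_per_type, params, seed = seed, mask = clf$mask,
                          library = shared_library())
  mean(aa_alphabet()[max.col(predict(clf, ev$x))] == ev$y)
}

# One chain_fragment wrapping a residue table built in code.
as_fragment <- function(residues, id = "frag") {
  structure(list(fragment_id = id, residues = residues),
            class = "chain_fragment")
}

# Ideal straight-backbone residue table with the given CA spacing; used where
# only topology (gaps, ordering) matters, not real geometry.
toy_residues <- function(n, chain = "A", start_resno = 1L, gap_after = integer(0),
                         gap_size = 5) {
  ca <- cbind(3.8 * seq_len(n), 0, 0)
  extra <- cumsum(seq_len(n) %in% (gap_after + 1L)) * gap_size
  ca[, 1] <- ca[, 1] + extra
  data.frame(chain = chain, resno = seq(start_resno, length.out = n), ins = "",
             restype = NA_character_,
             n_x = ca[, 1] - 1.33, n_y = 0.4, n_z = 0,
             ca_x = ca[, 1], ca_y = 0, ca_z = 0,
             c_x = ca[, 1] + 1.2, c_y = 0.8, c_z = 0.4,
             stringsAsFactors = FALSE)
}

# Dirichlet-profile generator for null-calibration experiments.
random_profile <- function(L, concentration = 3, floor_p = 1e-6) {
  p <- matrix(stats::rgamma(L * 20, concentration), L, 20)
  p <- p / rowSums(p)
  p <- pmax(p, floor_p)
  p / rowSums(p)
}

random_target <- function(M) paste(sample(aa_alphabet(), M, replace = TRUE),
                                   collapse = "")
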
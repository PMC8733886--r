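# 20-class residue-type classifier: a two-layer fully connected network
# (input -> ReLU hidden with dropout -> 20-way log-softmax) trained with Adam
# on the negative log-likelihood. The mask that defines the descriptor layout
# is stored with the weights so inputs and model can never drift apart.

#' Classifier configuration
#'
#' Defaults follow the reference training protocol: hidden width equal to the
#' input width, dropout probability 0.5 between the layers, Adam with learning
#' rate 1e-4, 1000 epochs, batch size 20, 10% validation split.
#'
#' @param input_dim Descriptor length (= mask `n_points`).
#' @param hidden_dim Hidden-layer width (default `input_dim`).
#' @param n_classes Number of residue classes (20).
#' @param dropout_p Dropout probability in training mode (default 0.5).
#' @param learning_rate Adam learning rate (default 1e-4).
#' @param epochs Training epochs (default 1000).
#' @param batch_size Minibatch size (default 20).
#' @param validation_fraction Held-out fraction (default 0.10).
#' @param seed RNG seed controlling initialization, shuffling and dropout.
#' @return List of class `classifier_config`.
#' @export
classifier_config <- function(input_dim, hidden_dim = input_dim, n_classes = 20L,
                              dropout_p = 0.5, learning_rate = 1e-4,
                              epochs = 1000L, batch_size = 20L,
                              validation_fraction = 0.10, seed = 1L) {
  stopifnot(input_dim > 0, hidden_dim > 0, n_classes > 0,
            dropout_p >= 0, dropout_p < 1,
            learning_rate > 0, epochs >= 1, batch_size >= 1,
            validation_fraction > 0, validation_fraction < 1)
  structure(list(input_dim = as.integer(input_dim),
                 hidden_dim = as.integer(hidden_dim),
                 n_classes = as.integer(n_classes), dropout_p = dropout_p,
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 validation_fraction = validation_fraction,
                 seed = as.integer(seed)),
            class = "classifier_config")
}

kaiming_init <- function(fan_in, fan_out) {
  lim <- sqrt(6 / fan_in)
  matrix(stats::runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
}

log_softmax_rows <- function(z) {
  m <- apply(z, 1, max)
  z <- z - m
  z - log(rowSums(exp(z)))
}

#' Forward pass of the residue-type network
#'
#' @param weights List with `W1`, `b1`, `W2`, `b2`.
#' @param x Numeric matrix (n x input_dim) or vector (one descriptor).
#' @param dropout_p Dropout probability; only applied when `training = TRUE`
#'   (inverted dropout). Inference is deterministic.
#' @param training Logical.
#' @return Matrix (n x n_classes) of log-probabilities (rows sum to 1 after
#'   exponentiation).
#' @export
mlp_forward <- function(weights, x, dropout_p = 0, training = FALSE) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != nrow(weights$W1))
    stop_classed(sprintf("descriptor length %d does not match classifier input_dim %d",
                         ncol(x), nrow(weights$W1)), "shape_mismatch")
  a1 <- pmax(x %*% weights$W1 + rep(weights$b1, each = nrow(x)), 0)
  if (training && dropout_p > 0) {
    mask <- matrix(stats::runif(length(a1)) >= dropout_p, nrow(a1), ncol(a1))
    a1 <- a1 * mask / (1 - dropout_p)
  }
  z2 <- a1 %*% weights$W2 + rep(weights$b2, each = nrow(x))
  log_softmax_rows(z2)
}

#' Fit the residue-type classifier
#'
#' Trains the two-layer network with Adam on the negative log-likelihood of
#' the log-softmax outputs. Deterministic for a given `config$seed`.
#'
#' @param x Descriptor matrix (n x input_dim).
#' @param y Labels: one-letter residue codes (in [aa_alphabet()]) or integer
#'   class indices 1..n_classes.
#' @param config A [classifier_config]. `input_dim` must equal `ncol(x)`.
#' @param mask The [build_grid_mask] object the descriptors were extracted
#'   with; stored in the fitted model.
#' @param map_kind Free-text provenance tag ("xray", "em", "synthetic", ...).
#' @param verbose Print a progress line every 10 epochs.
#' @return Object of class `residue_classifier` with weights, the mask,
#'   config and a per-epoch `history` (train/validation loss and accuracy).
#' @export
fit_residue_classifier <- function(x, y, config, mask = NULL,
                                   map_kind = "synthetic", verbose = FALSE) {
  stopifnot(inherits(config, "classifier_config"))
  x <- as.matrix(x)
  if (ncol(x) != config$input_dim)
    stop_classed(sprintf("x has %d columns but config$input_dim is %d",
                         ncol(x), config$input_dim), "shape_mismatch")
  if (is.character(y)) y <- match(y, AA)
  y <- as.integer(y)
  if (anyNA(y) || any(y < 1) || any(y > config$n_classes))
    stop_classed("labels outside the residue-type alphabet", "format_error")
  if (length(unique(y)) < 2)
    stop_classed("need at least 2 classes to train", "config_error")
  n <- nrow(x)
  if (n < config$batch_size)
    stop_classed(sprintf("fewer samples (%d) than batch_size (%d)", n,
                         config$batch_size), "config_error")

  set.seed(config$seed)
  perm <- sample.int(n)
  n_val <- max(1L, floor(config$validation_fraction * n))
  val_ix <- perm[seq_len(n_val)]
  tr_ix <- perm[-seq_len(n_val)]
  xtr <- x[tr_ix, , drop = FALSE]; ytr <- y[tr_ix]
  xva <- x[val_ix, , drop = FALSE]; yva <- y[val_ix]

  w <- list(W1 = kaiming_init(config$input_dim, config$hidden_dim),
            b1 = numeric(config$hidden_dim),
            W2 = kaiming_init(config$hidden_dim, config$n_classes),
            b2 = numeric(config$n_classes))
  adam <- list(m = lapply(w, function(p) p * 0), v = lapply(w, function(p) p * 0),
               t = 0L, beta1 = 0.9, beta2 = 0.999, eps = 1e-8)
  p_drop <- config$dropout_p
  ntr <- length(ytr)
  hist <- data.frame(epoch = seq_len(config$epochs), train_loss = NA_real_,
                     val_loss = NA_real_, train_acc = NA_real_, val_acc = NA_real_)

  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(ntr)
    ep_loss <- 0; ep_n <- 0L
    for (s in seq(1L, ntr, by = config$batch_size)) {
      bix <- ord[s:min(s + config$batch_size - 1L, ntr)]
      xb <- xtr[bix, , drop = FALSE]; yb <- ytr[bix]
      nb <- length(yb)
      # forward with dropout
      z1 <- xb %*% w$W1 + rep(w$b1, each = nb)
      a1 <- pmax(z1, 0)
      if (p_drop > 0) {
        dmask <- matrix(stats::runif(length(a1)) >= p_drop, nb, ncol(a1))
        a1d <- a1 * dmask / (1 - p_drop)
      } else a1d <- a1
      z2 <- a1d %*% w$W2 + rep(w$b2, each = nb)
      lp <- log_softmax_rows(z2)
      loss <- -mean(lp[cbind(seq_len(nb), yb)])
      if (!is.finite(loss))
        stop_classed(sprintf("NaN/Inf loss at epoch %d; lower the learning rate", ep),
                     "training_diverged")
      ep_loss <- ep_loss + loss * nb; ep_n <- ep_n + nb
      # backward
      soft <- exp(lp)
      soft[cbind(seq_len(nb), yb)] <- soft[cbind(seq_len(nb), yb)] - 1
      dz2 <- soft / nb
      gW2 <- crossprod(a1d, dz2)
      gb2 <- colSums(dz2)
      da1 <- dz2 %*% t(w$W2)
      if (p_drop > 0) da1 <- da1 * dmask / (1 - p_drop)
      dz1 <- da1 * (z1 > 0)
      gW1 <- crossprod(xb, dz1)
      gb1 <- colSums(dz1)
      g <- list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2)
      adam$t <- adam$t + 1L
      for (k in names(w)) {
        adam$m[[k]] <- adam$beta1 * adam$m[[k]] + (1 - adam$beta1) * g[[k]]
        adam$v[[k]] <- adam$beta2 * adam$v[[k]] + (1 - adam$beta2) * g[[k]]^2
        mhat <- adam$m[[k]] / (1 - adam$beta1^adam$t)
        vhat <- adam$v[[k]] / (1 - adam$beta2^adam$t)
        w[[k]] <- w[[k]] - config$learning_rate * mhat / (sqrt(vhat) + adam$eps)
      }
    }
    lp_tr <- mlp_forward(w, xtr)
    lp_va <- mlp_forward(w, xva)
    hist$train_loss[ep] <- ep_loss / ep_n
    hist$val_loss[ep] <- -mean(lp_va[cbind(seq_along(yva), yva)])
    hist$train_acc[ep] <- mean(max.col(lp_tr) == ytr)
    hist$val_acc[ep] <- mean(max.col(lp_va) == yva)
    if (verbose && ep %% 10 == 0)
      message(sprintf("epoch %d/%d: train loss %.4f acc %.3f | val loss %.4f acc %.3f",
                      ep, config$epochs, hist$train_loss[ep], hist$train_acc[ep],
                      hist$val_loss[ep], hist$val_acc[ep]))
  }
  structure(list(weights = w, mask = mask, config = config, history = hist,
                 map_kind = map_kind,
                 train_accuracy = hist$train_acc[config$epochs],
                 val_accuracy = hist$val_acc[config$epochs]),
            class = "residue_classifier")
}

#' @export
print.residue_classifier <- function(x, ...) {
  cat(sprintf("residue_classifier (%s maps): %d -> %d -> %d, dropout %.2f\n",
              x$map_kind, x$config$input_dim, x$config$hidden_dim,
              x$config$n_classes, x$config$dropout_p))
  cat(sprintf("  trained %d epochs (batch %d, lr %g, seed %d)\n",
              x$config$epochs, x$config$batch_size, x$config$learning_rate,
              x$config$seed))
  cat(sprintf("  final accuracy: train %.3f, validation %.3f\n",
              x$train_accuracy, x$val_accuracy))
  invisible(x)
}

#' @export
summary.residue_classifier <- function(object, ...) {
  print(object)
  h <- object$history
  cat("\nTraining history (last 5 epochs):\n")
  print(utils::tail(h, 5), row.names = FALSE)
  invisible(object$history)
}

#' @export
coef.residue_classifier <- function(object, ...) object$weights

#' Predict residue-type log-probabilities for descriptors
#'
#' @param object A `residue_classifier`.
#' @param newdata Descriptor matrix (n x input_dim) or single descriptor.
#' @param type `"logprob"` (default) or `"prob"`.
#' @param ... Unused.
#' @return Matrix n x 20, columns named by [aa_alphabet()].
#' @export
predict.residue_classifier <- function(object, newdata, type = c("logprob", "prob"), ...) {
  type <- match.arg(type)
  lp <- mlp_forward(object$weights, newdata)
  colnames(lp) <- AA[seq_len(ncol(lp))]
  if (type == "prob") exp(lp) else lp
}

#' Predict a per-residue probability profile for a traced model
#'
#' Extracts the masked-grid descriptor of every residue (map standardized with
#' [map_normalizer] over backbone-adjacent voxels), runs the classifier in
#' inference mode, floors probabilities at `floor_p` and renormalizes.
#' Fragments are processed longest-first; residues whose descriptors cannot
#' be sampled are excluded and listed in `skipped`.
#'
#' @param classifier A `residue_classifier` (must carry its mask).
#' @param fragments List of `chain_fragment`s (see [extract_fragments]).
#' @param map A [density_map].
#' @param floor_p Probability floor (default 1e-6) applied before log-scoring
#'   downstream so sums of logs stay finite.
#' @return Object of class `probability_profile`: matrix `p` (n x 20),
#'   data frame `residues` (fragment, chain, resno, ins, row index), vector
#'   `fragment_sizes`, list `skipped`.
#' @export
predict_profile <- function(classifier, fragments, map, floor_p = 1e-6) {
  stopifnot(inherits(classifier, "residue_classifier"))
  if (is.null(classifier$mask))
    stop_classed("classifier carries no grid mask; cannot extract descriptors",
                 "config_error")
  mask <- classifier$mask
  lens <- vapply(fragments, function(f) nrow(f$residues), integer(1))
  fragments <- fragments[order(-lens)]
  bb <- do.call(rbind, lapply(fragments, function(f) {
    r <- f$residues
    rbind(as.matrix(r[, c("n_x", "n_y", "n_z")]),
          as.matrix(r[, c("ca_x", "ca_y", "ca_z")]),
          as.matrix(r[, c("c_x", "c_y", "c_z")]))
  }))
  norm <- map_normalizer(map, bb)
  rows <- list(); meta <- list(); skipped <- list()
  for (f in fragments) {
    r <- f$residues
    part <- 1L; gap_open <- FALSE; frag_has_rows <- FALSE
    for (i in seq_len(nrow(r))) {
      fr <- build_local_frame(c(r$n_x[i], r$n_y[i], r$n_z[i]),
                              c(r$ca_x[i], r$ca_y[i], r$ca_z[i]),
                              c(r$c_x[i], r$c_y[i], r$c_z[i]))
      d <- extract_descriptor(map, fr, mask, norm)
      if (is.null(d)) {
        skipped[[length(skipped) + 1L]] <-
          list(fragment = f$fragment_id, resno = r$resno[i])
        # a mid-fragment gap breaks the ungapped-register contract: the
        # remaining residues continue as a new sub-fragment
        if (frag_has_rows) gap_open <- TRUE
        next
      }
      if (gap_open) { part <- part + 1L; gap_open <- FALSE }
      frag_has_rows <- TRUE
      fid <- if (part == 1L) f$fragment_id else sprintf("%s#%d", f$fragment_id, part)
      rows[[length(rows) + 1L]] <- d
      meta[[length(meta) + 1L]] <- data.frame(
        fragment = fid, chain = r$chain[i], resno = r$resno[i],
        ins = r$ins[i], stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0)
    stop_classed("no residue yielded an extractable descriptor", "empty_profile")
  x <- do.call(rbind, rows)
  p <- predict(classifier, x, type = "prob")
  p <- pmax(p, floor_p)
  p <- p / rowSums(p)
  res <- do.call(rbind, meta)
  if (length(skipped) > 0)
    message(sprintf("predict_profile: %d residue(s) skipped (unsampleable descriptors)",
                    length(skipped)))
  probability_profile(p, res, skipped = skipped)
}

#' Construct a probability profile
#'
#' @param p Matrix (n x 20) of per-residue probabilities (rows sum to 1).
#' @param residues Data frame with a `fragment` column (plus any identity
#'   columns), one row per profile row, fragments contiguous.
#' @param skipped Optional list describing residues excluded upstream.
#' @return `probability_profile` object.
#' @export
probability_profile <- function(p, residues, skipped = list()) {
  p <- as.matrix(p)
  stopifnot(ncol(p) == 20, nrow(p) == nrow(residues),
            all(abs(rowSums(p) - 1) < 1e-6), all(p > 0))
  colnames(p) <- AA
  structure(list(p = p, residues = residues,
                 fragment_sizes = table(factor(residues$fragment,
                                               levels = unique(residues$fragment))),
                 skipped = skipped),
            class = "probability_profile")
}

#' @export
print.probability_profile <- function(x, ...) {
  cat(sprintf("probability_profile: %d residues in %d fragment(s)\n",
              nrow(x$p), length(x$fragment_sizes)))
  sz <- as.integer(x$fragment_sizes)
  cat(sprintf("  fragment sizes: %s\n", paste(sz, collapse = ", ")))
  if (length(x$skipped) > 0)
    cat(sprintf("  %d residue(s) skipped\n", length(x$skipped)))
  invisible(x)
}

#' Save / load a trained classifier
#'
#' The weight file is a versioned JSON container holding both layers, the
#' grid mask and training metadata. Loading verifies internal consistency
#' (mask size vs input dimension).
#'
#' @param classifier A `residue_classifier`.
#' @param path Output/input path.
#' @return `save_classifier`: `path` invisibly; `load_classifier`: the model.
#' @export
save_classifier <- function(classifier, path) {
  stopifnot(inherits(classifier, "residue_classifier"))
  payload <- list(
    format = "mapseqid_classifier", version = 1L,
    config = unclass(classifier$config),
    map_kind = classifier$map_kind,
    train_accuracy = classifier$train_accuracy,
    val_accuracy = classifier$val_accuracy,
    weights = lapply(classifier$weights, function(w)
      if (is.matrix(w)) list(dim = dim(w), data = as.vector(w)) else list(dim = length(w), data = as.vector(w))),
    mask = if (!is.null(classifier$mask)) list(
      offsets = as.vector(classifier$mask$offsets),
      n_points = classifier$mask$n_points,
      spacing = classifier$mask$spacing,
      inclusion_radius = classifier$mask$inclusion_radius) else NULL)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  if (!file.exists(path))
    stop_classed(sprintf("weights file not found: %s", path), "format_error")
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(j$format) || j$format != "mapseqid_classifier")
    stop_classed("not a mapseqid classifier weight file", "format_error")
  cfg <- do.call(classifier_config, j$config[c("input_dim", "hidden_dim", "n_classes",
                                               "dropout_p", "learning_rate", "epochs",
                                               "batch_size", "validation_fraction",
                                               "seed")])
  w <- lapply(j$weights, function(entry) {
    if (length(entry$dim) == 2) matrix(entry$data, entry$dim[1], entry$dim[2])
    else as.numeric(entry$data)
  })
  mask <- NULL
  if (!is.null(j$mask)) {
    off <- matrix(as.integer(j$mask$offsets), ncol = 3)
    mask <- structure(list(offsets = off, spacing = j$mask$spacing,
                           inclusion_radius = j$mask$inclusion_radius,
                           n_points = nrow(off)),
                      class = "grid_mask")
    if (mask$n_points != cfg$input_dim)
      stop_classed(sprintf("stored mask has %d points but input_dim is %d",
                           mask$n_points, cfg$input_dim), "format_error")
  }
  structure(list(weights = w, mask = mask, config = cfg, history = NULL,
                 map_kind = j$map_kind,
                 train_accuracy = j$train_accuracy, val_accuracy = j$val_accuracy),
            class = "residue_classifier")
}
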
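# Whole-fragment sequence assignment: ungapped alignment of a fragment's
# predicted residue-type probabilities against a target sequence, scored as a
# sum of log probabilities, standardized to a Z-score against the analytic
# null of a random target, and converted to an extreme-value p-value over the
# number of alternative alignments (reduced by a redundancy factor because
# overlapping alignments are not independent).

#' Background residue-type frequencies
#'
#' @param target Target amino-acid sequence (single string), or `NULL`.
#' @param mode `"target"` (default): add-one-smoothed composition of the
#'   target itself, the natural model for "a random target sequence";
#'   `"uniform"`: 1/20 everywhere.
#' @return Named numeric 20-vector summing to 1.
#' @export
background_frequencies <- function(target = NULL, mode = c("target", "uniform")) {
  mode <- match.arg(mode)
  if (mode == "uniform" || is.null(target)) {
    q <- rep(1 / 20, 20)
  } else {
    idx <- seq_to_idx(target)
    counts <- tabulate(idx[!is.na(idx)], nbins = 20)
    q <- (counts + 1) / (sum(counts) + 20)
  }
  names(q) <- AA
  q
}

# log-probability matrix of a profile block, with a 21st wildcard column used
# for 'X' (scored as log background probability, i.e. log 1/20).
logp_extended <- function(p) {
  lp <- log(p)
  cbind(lp, rep(log(1 / 20), nrow(lp)))
}

target_indices <- function(target) {
  idx <- seq_to_idx(target)
  idx[is.na(idx)] <- 21L
  idx
}

#' Score one ungapped fragment-to-window alignment
#'
#' `score = sum_i log p_i(a_i)` over consecutive fragment positions.
#'
#' @param p Probability matrix (L x 20) of the fragment (rows sum to 1,
#'   entries floored > 0).
#' @param window Amino-acid string (or character vector) of length L.
#' @return The log-probability score.
#' @export
score_alignment <- function(p, window) {
  if (length(window) == 1L) window <- strsplit(window, "")[[1]]
  if (length(window) != nrow(p))
    stop_classed(sprintf("window length %d does not match fragment length %d",
                         length(window), nrow(p)), "shape_mismatch")
  lp <- logp_extended(as.matrix(p))
  idx <- target_indices(paste(window, collapse = ""))
  sum(lp[cbind(seq_len(nrow(lp)), idx)])
}

#' Analytic null moments of the alignment score
#'
#' Mean and standard deviation of the score of a fragment aligned to a random
#' target drawn i.i.d. from background frequencies `q`, assuming independent
#' positions: `mu = sum_i sum_a q(a) log p_i(a)` and
#' `sigma^2 = sum_i Var_a[log p_i(a)]`.
#'
#' @param p Probability matrix (L x 20).
#' @param q Background 20-vector (sums to 1).
#' @return List of class `null_moments`: `mu`, `sigma`, `background`,
#'   `degenerate` (TRUE when sigma is numerically zero).
#' @export
null_moments <- function(p, q) {
  p <- as.matrix(p)
  q <- as.numeric(q)
  stopifnot(length(q) == 20, all(q >= 0), abs(sum(q) - 1) < 1e-8)
  lp <- log(p)
  e1 <- lp %*% q          # per-position E[log p_i(a)]
  e2 <- (lp^2) %*% q
  mu <- sum(e1)
  var <- sum(e2 - e1^2)
  sigma <- sqrt(max(var, 0))
  # threshold well above float cancellation noise in e2 - e1^2: genuinely
  # informative profiles have sigma of order 0.1 per position and larger
  structure(list(mu = mu, sigma = sigma, background = q,
                 degenerate = sigma < 1e-6),
            class = "null_moments")
}

#' Best whole-fragment alignment to a target sequence
#'
#' Evaluates all `M - L + 1` ungapped offsets and returns the best-scoring
#' one (ties broken by the smallest offset) with its Z-score against the
#' analytic null of [null_moments].
#'
#' @param p Probability matrix (L x 20) of the fragment.
#' @param target Target amino-acid sequence (single string).
#' @param q Background frequencies; default derived from the target.
#' @return List: `offset` (0-based), `score`, `z` (`NA` when the null is
#'   degenerate), `n_alignments`, `moments`, `scores` (all offsets).
#' @export
best_alignment <- function(p, target, q = background_frequencies(target)) {
  p <- as.matrix(p)
  L <- nrow(p)
  idx <- target_indices(target)
  M <- length(idx)
  if (L > M)
    stop_classed(sprintf("fragment (L=%d) longer than target (M=%d)", L, M),
                 "no_alignment")
  lp <- logp_extended(p)
  n_off <- M - L + 1L
  # position-wise lookup, accumulated per offset
  scores <- numeric(n_off)
  for (i in seq_len(L)) {
    scores <- scores + lp[i, idx[i:(i + n_off - 1L)]]
  }
  best <- which.max(scores)        # which.max returns the first (smallest offset)
  mom <- null_moments(p, q)
  z <- if (mom$degenerate) NA_real_ else (scores[best] - mom$mu) / mom$sigma
  list(offset = best - 1L, score = scores[best], z = z,
       n_alignments = n_off, moments = mom, scores = scores)
}

#' Extreme-value p-value of a best-alignment Z-score
#'
#' The best of `n_alignments` alternative alignments is compared against the
#' maximum of `n_eff = n_alignments / reduction_factor` independent standard
#' normals: `p = 1 - Phi(z)^n_eff`, evaluated in log space. The default
#' reduction factor of 10 compensates for the statistical redundancy of
#' overlapping alignments. The classical Gumbel-Fisher-Tippett form is the
#' asymptotic limit of this expression for large `n_eff`.
#'
#' @param z Z-score (may be `NA` for degenerate nulls; then `p = 1`).
#' @param n_alignments Number of alternative alignments considered (>= 1).
#' @param reduction_factor Redundancy correction (default 10).
#' @return p-value in (0, 1].
#' @export
extreme_value_p <- function(z, n_alignments, reduction_factor = 10) {
  stopifnot(n_alignments >= 1, reduction_factor > 0)
  if (is.na(z) || !is.finite(z)) return(1)
  n_eff <- n_alignments / reduction_factor
  p <- -expm1(n_eff * stats::pnorm(z, log.p = TRUE))
  min(max(p, .Machine$double.xmin), 1)
}

#' Assign sequence register to model fragments
#'
#' For every fragment in the profile, finds the best forward (and optionally
#' reversed) whole-fragment alignment against the target sequence, computes
#' Z-scores and extreme-value p-values per orientation, and assigns residue
#' types from the target wherever the better orientation reaches
#' `p_threshold`. Reversal flips the profile-to-sequence mapping only; the
#' density descriptors are not recomputed on a reversed backbone.
#'
#' @param profile A [probability_profile].
#' @param target Target amino-acid sequence (single string).
#' @param target_id Identifier used in the report (default `"target"`).
#' @param p_threshold Acceptance threshold on the p-value (default 0.1, below
#'   which assignment is considered unambiguous).
#' @param reduction_factor Redundancy correction for [extreme_value_p].
#' @param try_reverse Also score the reversed orientation (default TRUE).
#' @param background `"target"` or `"uniform"` (see [background_frequencies]).
#' @return Object of class `assignment_set`: data frame `results` (one row
#'   per fragment and orientation), list `assigned` (per fragment: character
#'   vector of assigned types or `NA`s), data frame `conflicts`.
#' @export
assign_model <- function(profile, target, target_id = "target",
                         p_threshold = 0.1, reduction_factor = 10,
                         try_reverse = TRUE,
                         background = c("target", "uniform")) {
  stopifnot(inherits(profile, "probability_profile"))
  background <- match.arg(background)
  q <- background_frequencies(target, background)
  M <- nchar(target)
  frag_ids <- names(profile$fragment_sizes)
  rows <- list(); assigned <- list()
  accepted <- list()
  tletters <- strsplit(toupper(target), "")[[1]]
  any_fits <- FALSE
  for (fid in frag_ids) {
    sel <- profile$residues$fragment == fid
    pblock <- profile$p[sel, , drop = FALSE]
    L <- nrow(pblock)
    assigned[[fid]] <- rep(NA_character_, L)
    if (L > M) next
    any_fits <- TRUE
    ors <- c("forward", if (try_reverse) "reversed")
    cand <- list()
    for (orient in ors) {
      pb <- if (orient == "reversed") pblock[L:1, , drop = FALSE] else pblock
      ba <- best_alignment(pb, target, q)
      pv <- extreme_value_p(ba$z, ba$n_alignments, reduction_factor)
      cand[[orient]] <- list(ba = ba, p = pv)
      rows[[length(rows) + 1L]] <- data.frame(
        fragment_id = fid, target_id = target_id, orientation = orient,
        offset = ba$offset, score = ba$score,
        z = if (is.na(ba$z)) NA_real_ else ba$z, p_value = pv,
        n_alignments = ba$n_alignments,
        n_effective = ba$n_alignments / reduction_factor,
        accepted = FALSE, stringsAsFactors = FALSE)
    }
    ps <- vapply(cand, function(cc) cc$p, numeric(1))
    bestor <- names(cand)[which.min(ps)]
    if (ps[bestor] <= p_threshold) {
      ba <- cand[[bestor]]$ba
      win <- tletters[(ba$offset + 1):(ba$offset + L)]
      assigned[[fid]] <- if (bestor == "reversed") rev(win) else win
      accepted[[fid]] <- list(orientation = bestor, offset = ba$offset, L = L)
    }
  }
  if (!any_fits && length(frag_ids) > 0)
    stop_classed("all fragments are longer than the target sequence", "no_alignment")
  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  # mark accepted rows properly
  results$accepted <- FALSE
  for (fid in names(accepted)) {
    a <- accepted[[fid]]
    hit <- results$fragment_id == fid & results$orientation == a$orientation
    results$accepted[hit] <- TRUE
  }
  # conflicts: accepted fragments whose target ranges overlap
  conflicts <- data.frame(fragment_a = character(0), fragment_b = character(0),
                          overlap_start = integer(0), overlap_end = integer(0),
                          stringsAsFactors = FALSE)
  fids <- names(accepted)
  if (length(fids) > 1) {
    for (i in seq_along(fids)[-length(fids)]) for (j in (i + 1):length(fids)) {
      a <- accepted[[fids[i]]]; b <- accepted[[fids[j]]]
      s <- max(a$offset, b$offset)
      e <- min(a$offset + a$L, b$offset + b$L) - 1L
      if (s <= e)
        conflicts[nrow(conflicts) + 1L, ] <- list(fids[i], fids[j], s, e)
    }
  }
  structure(list(results = results, assigned = assigned, conflicts = conflicts,
                 target_id = target_id, p_threshold = p_threshold),
            class = "assignment_set")
}

#' @export
print.assignment_set <- function(x, ...) {
  cat(sprintf("assignment_set vs '%s' (p threshold %g):\n", x$target_id,
              x$p_threshold))
  r <- x$results
  for (i in seq_len(nrow(r))) {
    cat(sprintf("  %s %-8s offset %4d  score %8.2f  Z %6.2f  p %.3g%s\n",
                r$fragment_id[i], r$orientation[i], r$offset[i] + 1L,
                r$score[i], ifelse(is.na(r$z[i]), NaN, r$z[i]), r$p_value[i],
                if (r$accepted[i]) "  [assigned]" else ""))
  }
  if (nrow(x$conflicts) > 0)
    cat(sprintf("  %d overlapping assignment conflict(s)\n", nrow(x$conflicts)))
  invisible(x)
}
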
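# Database queries from a probability profile: the profile is expanded into a
# synthetic ungapped MSA whose column residue-type fractions reproduce the
# predicted probabilities, converted to a profile-HMM with hmmbuild and run
# against a FASTA database with hmmsearch (default parameters). A
# dependency-free internal scanner reusing the whole-fragment alignment
# statistics is provided as a fallback ranking engine.

#' Expand a probability profile into a synthetic MSA
#'
#' Per column, integer letter counts are the largest-remainder apportionment
#' of `K * p(a)` (ties broken alphabetically), so fractions match the
#' probabilities to within 1/(2K). Letters are distributed across rows by a
#' fixed deterministic schedule (per column, letters sorted by descending
#' count then alphabet, filled row by row), making the MSA byte-reproducible.
#' Multi-fragment profiles are concatenated longest-fragment-first with no
#' separator columns.
#'
#' @param profile A [probability_profile] (or bare probability matrix).
#' @param K MSA depth (number of rows, default 100; >= 20 recommended).
#' @return Object of class `synthetic_msa`: character matrix `letters`
#'   (K x n_columns), `K`, `n_columns`.
#' @export
profile_to_msa <- function(profile, K = 100L) {
  p <- if (inherits(profile, "probability_profile")) profile$p else as.matrix(profile)
  if (is.null(p) || nrow(p) == 0)
    stop_classed("empty profile", "empty_profile")
  K <- as.integer(K)
  stopifnot(K >= 1)
  n <- nrow(p)
  m <- matrix("", nrow = K, ncol = n)
  for (j in seq_len(n)) {
    counts <- apportion_counts(p[j, ], K)
    ord <- order(-counts, AA)
    m[, j] <- rep(AA[ord], counts[ord])
  }
  structure(list(letters = m, K = K, n_columns = n), class = "synthetic_msa")
}

# Largest-remainder apportionment of K among 20 classes; ties on equal
# remainders go to the alphabetically first type.
apportion_counts <- function(p, K) {
  exact <- K * p / sum(p)
  counts <- floor(exact)
  rem <- exact - counts
  short <- K - sum(counts)
  if (short > 0) {
    ord <- order(-rem, AA)
    counts[ord[seq_len(short)]] <- counts[ord[seq_len(short)]] + 1
  }
  as.integer(counts)
}

#' Write a synthetic MSA in Stockholm format
#'
#' @param msa A `synthetic_msa`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_stockholm <- function(msa, path) {
  stopifnot(inherits(msa, "synthetic_msa"))
  ids <- sprintf("seq%04d", seq_len(msa$K))
  rows <- apply(msa$letters, 1, paste, collapse = "")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# STOCKHOLM 1.0", con)
  writeLines(sprintf("%-10s %s", ids, rows), con)
  writeLines("//", con)
  invisible(path)
}

#' Is the HMMER suite available?
#'
#' @return TRUE if both `hmmbuild` and `hmmsearch` are on the PATH.
#' @export
hmmer_available <- function() {
  nzchar(Sys.which("hmmbuild")) && nzchar(Sys.which("hmmsearch"))
}

#' Query a sequence database with HMMER
#'
#' Writes the MSA in Stockholm format, builds a profile-HMM with `hmmbuild`
#' (default configuration) and scans the database with `hmmsearch` (default
#' parameters). Targets are ranked by their best-single-domain E-value and
#' the `top_n` lowest are returned.
#'
#' @param msa A `synthetic_msa` (see [profile_to_msa]).
#' @param db_path Path to the FASTA database.
#' @param top_n Number of hits to return (default 3).
#' @return Data frame of class `search_hits`: `sequence_id`, `e_value`
#'   (best single domain), `full_e_value`, `score`, sorted ascending by
#'   `e_value`; attribute `engine = "hmmer"`.
#' @export
hmmer_search <- function(msa, db_path, top_n = 3L) {
  if (!hmmer_available())
    stop_classed(paste("HMMER (hmmbuild/hmmsearch) not found on PATH;",
                       "use internal_search() instead"), "capability_error")
  if (!file.exists(db_path))
    stop_classed(sprintf("database not found: %s", db_path), "format_error")
  td <- tempfile("hmmq")
  dir.create(td)
  on.exit(unlink(td, recursive = TRUE))
  sto <- file.path(td, "query.sto")
  hmm <- file.path(td, "query.hmm")
  tbl <- file.path(td, "hits.tbl")
  write_stockholm(msa, sto)
  out1 <- suppressWarnings(system2(Sys.which("hmmbuild"),
                                   c("--amino", shQuote(hmm), shQuote(sto)),
                                   stdout = TRUE, stderr = TRUE))
  if (!is.null(attr(out1, "status")) && attr(out1, "status") != 0)
    stop_classed(paste("hmmbuild failed:", paste(out1, collapse = "\n")),
                 "tool_error")
  out2 <- suppressWarnings(system2(Sys.which("hmmsearch"),
                                   c("--tblout", shQuote(tbl),
                                     shQuote(hmm), shQuote(db_path)),
                                   stdout = TRUE, stderr = TRUE))
  if (!is.null(attr(out2, "status")) && attr(out2, "status") != 0)
    stop_classed(paste("hmmsearch failed:", paste(out2, collapse = "\n")),
                 "tool_error")
  lines <- readLines(tbl)
  lines <- lines[!startsWith(lines, "#")]
  hits <- if (length(lines) == 0) {
    data.frame(sequence_id = character(0), e_value = numeric(0),
               full_e_value = numeric(0), score = numeric(0),
               stringsAsFactors = FALSE)
  } else {
    f <- strsplit(trimws(lines), "\\s+")
    data.frame(sequence_id = vapply(f, `[`, "", 1),
               e_value = as.numeric(vapply(f, `[`, "", 8)),
               full_e_value = as.numeric(vapply(f, `[`, "", 5)),
               score = as.numeric(vapply(f, `[`, "", 6)),
               stringsAsFactors = FALSE)
  }
  hits <- hits[order(hits$e_value, hits$full_e_value), , drop = FALSE]
  hits <- utils::head(hits, top_n)
  rownames(hits) <- NULL
  structure(hits, class = c("search_hits", "data.frame"), engine = "hmmer")
}

#' Rank database sequences with the internal whole-profile scanner
#'
#' Dependency-free fallback: for every database sequence long enough, the
#' best ungapped whole-profile alignment is found ([best_alignment]) and
#' converted to an extreme-value p-value; hits are ranked by p-value (the
#' reported statistic is a p-value, not an E-value). Multi-fragment profiles
#' are scanned as one concatenated block.
#'
#' @param profile A [probability_profile] (or probability matrix).
#' @param db A `sequence_db` (see [read_fasta]).
#' @param top_n Number of hits to return (default 3).
#' @param reduction_factor Redundancy correction (default 10).
#' @param background `"target"` or `"uniform"` per-sequence background.
#' @return Data frame of class `search_hits`: `sequence_id`, `p_value`, `z`,
#'   `score`, `offset`, ascending by `p_value`; attribute `engine = "internal"`.
#' @export
internal_search <- function(profile, db, top_n = 3L, reduction_factor = 10,
                            background = c("target", "uniform")) {
  background <- match.arg(background)
  p <- if (inherits(profile, "probability_profile")) profile$p else as.matrix(profile)
  if (is.null(p) || nrow(p) == 0) stop_classed("empty profile", "empty_profile")
  if (nrow(db) == 0) stop_classed("empty database", "format_error")
  L <- nrow(p)
  lens <- nchar(db$seq)
  usable <- which(lens >= L)
  if (length(usable) == 0)
    stop_classed(sprintf("profile (L=%d) longer than every database sequence", L),
                 "no_alignment")
  rows <- lapply(usable, function(i) {
    q <- background_frequencies(db$seq[i], background)
    ba <- best_alignment(p, db$seq[i], q)
    pv <- extreme_value_p(ba$z, ba$n_alignments, reduction_factor)
    data.frame(sequence_id = db$id[i], p_value = pv,
               z = if (is.na(ba$z)) NA_real_ else ba$z,
               score = ba$score, offset = ba$offset, stringsAsFactors = FALSE)
  })
  hits <- do.call(rbind, rows)
  ord <- order(hits$p_value, -ifelse(is.na(hits$z), -Inf, hits$z))
  hits <- utils::head(hits[ord, , drop = FALSE], top_n)
  rownames(hits) <- NULL
  structure(hits, class = c("search_hits", "data.frame"), engine = "internal")
}

#' @export
print.search_hits <- function(x, ...) {
  eng <- attr(x, "engine")
  cat(sprintf("search_hits (%s engine), %d hit(s):\n", eng, nrow(x)))
  for (i in seq_len(nrow(x))) {
    if (identical(eng, "hmmer"))
      cat(sprintf("  %2d. %-20s best-domain E-value %.3g (score %.1f)\n",
                  i, x$sequence_id[i], x$e_value[i], x$score[i]))
    else
      cat(sprintf("  %2d. %-20s p-value %.3g (Z %.2f, offset %d)\n",
                  i, x$sequence_id[i], x$p_value[i], x$z[i], x$offset[i] + 1L))
  }
  invisible(x)
}
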
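# Backbone model reading, chain-fragment extraction, assigned-model writing.
# PDB/mmCIF parsing is delegated to bio3d; this module only regroups atoms
# into residues and residues into continuous main-chain fragments.

# A residue table has one row per residue with columns:
#   chain, resno, ins, restype (one-letter or NA), and the nine backbone
#   coordinates n_x..c_z. A chain_fragment wraps a residue table with an id.

#' Read a backbone model from PDB or mmCIF
#'
#' Keeps, per residue, the first altloc of each of the N, CA and C backbone
#' atoms. Residues missing any of the three are dropped with a warning; they
#' split fragments downstream.
#'
#' @param path Path to a `.pdb` or `.cif` file.
#' @return Data frame with one row per complete backbone residue.
#' @export
read_backbone_model <- function(path) {
  if (!file.exists(path))
    stop_classed(sprintf("model file not found: %s", path), "format_error")
  ext <- tolower(tools::file_ext(path))
  pdb <- if (ext %in% c("cif", "mmcif")) {
    bio3d::read.cif(path, verbose = FALSE)
  } else {
    bio3d::read.pdb(path, verbose = FALSE)
  }
  at <- pdb$atom
  at <- at[at$elety %in% c("N", "CA", "C"), , drop = FALSE]
  if (nrow(at) == 0)
    stop_classed("model contains no N/CA/C backbone atoms", "empty_model")
  ins <- at$insert
  ins[is.na(ins)] <- ""
  key <- paste(at$chain, at$resno, ins, sep = "\r")
  # first altloc wins: keep first occurrence of each (residue, atom) pair
  first <- !duplicated(paste(key, at$elety, sep = "\r"))
  at <- at[first, , drop = FALSE]
  key <- key[first]
  res_keys <- unique(key)
  rows <- lapply(res_keys, function(k) {
    sub <- at[key == k, , drop = FALSE]
    if (!all(c("N", "CA", "C") %in% sub$elety)) return(NULL)
    g <- function(a, col) sub[[col]][match(a, sub$elety)]
    restype <- AA1[sub$resid[1]]
    if (is.na(restype)) restype <- NA_character_
    data.frame(chain = sub$chain[1], resno = sub$resno[1],
               ins = if (is.na(sub$insert[1])) "" else sub$insert[1],
               restype = restype,
               n_x = g("N", "x"), n_y = g("N", "y"), n_z = g("N", "z"),
               ca_x = g("CA", "x"), ca_y = g("CA", "y"), ca_z = g("CA", "z"),
               c_x = g("C", "x"), c_y = g("C", "y"), c_z = g("C", "z"),
               stringsAsFactors = FALSE)
  })
  dropped <- sum(vapply(rows, is.null, logical(1)))
  if (dropped > 0)
    warning(sprintf("%d residue(s) missing N/CA/C backbone atoms were dropped", dropped))
  res <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(res) || nrow(res) == 0)
    stop_classed("no residue with complete N/CA/C backbone in model", "empty_model")
  rownames(res) <- NULL
  res
}

#' Split a residue table into continuous chain fragments
#'
#' A new fragment starts at a chain-identifier change, a residue-number gap
#' larger than 1, or a C(i)->N(i+1) distance above `break_distance` (the
#' peptide bond is ~1.33 Angstrom). Fragments are returned sorted by
#' descending length (stable for ties), the order in which downstream
#' profiling processes them.
#'
#' @param residues Residue table from [read_backbone_model] (or built in code).
#' @param break_distance Chain-break threshold in Angstrom (default 2.0).
#' @return List of `chain_fragment` objects (`fragment_id`, `residues`).
#' @export
extract_fragments <- function(residues, break_distance = 2.0) {
  if (is.null(residues) || nrow(residues) == 0)
    stop_classed("no residues to extract fragments from", "empty_model")
  n <- nrow(residues)
  brk <- logical(n)
  if (n > 1) {
    i <- seq_len(n - 1)
    dcn <- sqrt((residues$c_x[i] - residues$n_x[i + 1])^2 +
                (residues$c_y[i] - residues$n_y[i + 1])^2 +
                (residues$c_z[i] - residues$n_z[i + 1])^2)
    brk[i + 1] <- residues$chain[i + 1] != residues$chain[i] |
      (residues$resno[i + 1] - residues$resno[i]) > 1 |
      dcn > break_distance
  }
  grp <- cumsum(c(TRUE, brk[-1]))
  frags <- lapply(split(seq_len(n), grp), function(ix) {
    r <- residues[ix, , drop = FALSE]
    rownames(r) <- NULL
    structure(list(
      fragment_id = sprintf("%s_%d-%d", r$chain[1], r$resno[1], r$resno[nrow(r)]),
      residues = r), class = "chain_fragment")
  })
  lens <- vapply(frags, function(f) nrow(f$residues), integer(1))
  frags <- frags[order(-lens)]
  names(frags) <- NULL
  frags
}

#' @export
print.chain_fragment <- function(x, ...) {
  cat(sprintf("chain_fragment %s: %d residues (chain %s, %d-%d)\n",
              x$fragment_id, nrow(x$residues), x$residues$chain[1],
              x$residues$resno[1], x$residues$resno[nrow(x$residues)]))
  invisible(x)
}

#' Write a model with assigned residue types
#'
#' Writes the backbone (N, CA, C) with residue names renamed to the assigned
#' types, optionally adding a CB stub (ideal frame position) for non-glycine
#' residues. Backbone coordinates are never modified.
#'
#' @param fragments List of `chain_fragment`s.
#' @param types List of character vectors (one per fragment) of one-letter
#'   assigned residue types, or `NA` entries to keep the existing name (UNK
#'   when unknown).
#' @param path Output PDB path.
#' @param cb_stubs Add CB atoms at the ideal local-frame position (default TRUE).
#' @param library Side-chain library (for the CB position); default bundled.
#' @return `path`, invisibly.
#' @export
write_model_with_sequence <- function(fragments, types, path, cb_stubs = TRUE,
                                      library = NULL) {
  stopifnot(length(fragments) == length(types))
  if (cb_stubs && is.null(library)) library <- read_sidechain_library()
  xyz <- numeric(0); elety <- character(0); resid <- character(0)
  chain <- character(0); resno <- integer(0); elesy <- character(0)
  insert <- character(0)
  for (fi in seq_along(fragments)) {
    r <- fragments[[fi]]$residues
    tt <- types[[fi]]
    if (length(tt) == 1L && is.na(tt[1])) tt <- rep(NA_character_, nrow(r))
    stopifnot(length(tt) == nrow(r))
    for (i in seq_len(nrow(r))) {
      one <- if (!is.na(tt[i])) tt[i] else r$restype[i]
      res3 <- if (!is.na(one) && one %in% AA) AA3[[one]] else "UNK"
      n <- c(r$n_x[i], r$n_y[i], r$n_z[i])
      ca <- c(r$ca_x[i], r$ca_y[i], r$ca_z[i])
      cc <- c(r$c_x[i], r$c_y[i], r$c_z[i])
      coords <- rbind(n, ca, cc)
      names_i <- c("N", "CA", "C")
      sym_i <- c("N", "C", "C")
      if (cb_stubs && !is.na(one) && one %in% AA && one != "G") {
        cb_local <- library[library$restype == one & library$rotamer == 0 &
                              library$atom == "CB", c("x", "y", "z")]
        if (nrow(cb_local) == 1) {
          fr <- build_local_frame(n, ca, cc)
          R <- cbind(fr$e_x, fr$e_y, fr$e_z)
          coords <- rbind(coords, ca + as.vector(R %*% as.numeric(cb_local[1, ])))
          names_i <- c(names_i, "CB")
          sym_i <- c(sym_i, "C")
        }
      }
      k <- nrow(coords)
      xyz <- c(xyz, as.vector(t(coords)))
      elety <- c(elety, names_i)
      elesy <- c(elesy, sym_i)
      resid <- c(resid, rep(res3, k))
      chain <- c(chain, rep(r$chain[i], k))
      resno <- c(resno, rep(r$resno[i], k))
      insert <- c(insert, rep(r$ins[i], k))
    }
  }
  bio3d::write.pdb(file = path, xyz = xyz, resno = resno, resid = resid,
                   chain = chain, elety = elety, elesy = elesy,
                   insert = ifelse(insert == "", NA, insert))
  invisible(path)
}
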
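# Backbone-aligned local frames, the side-chain grid mask, and extraction of
# fixed-length masked-grid density descriptors.
#
# The local frame is centred at CA and spanned by e_x = unit(CA - N),
# e_y = unit((CA - N) x (C - CA)) (the N-CA-C plane normal) and
# e_z = e_x x e_y. The mask is the set of lattice points (1 Angstrom spacing
# by default) lying within an inclusion radius of any side-chain atom of any
# residue type in a frame-aligned side-chain library; the same mask defines
# the classifier input layout, so it is persisted with trained weights.

#' Build the backbone-aligned local frame of a residue
#'
#' @param n_xyz,ca_xyz,c_xyz Orthogonal Angstrom coordinates of the N, CA and
#'   C backbone atoms.
#' @return List with `origin` (CA) and orthonormal right-handed `e_x`, `e_y`,
#'   `e_z`.
#' @export
build_local_frame <- function(n_xyz, ca_xyz, c_xyz) {
  n_xyz <- as.numeric(n_xyz); ca_xyz <- as.numeric(ca_xyz); c_xyz <- as.numeric(c_xyz)
  if (any(!is.finite(c(n_xyz, ca_xyz, c_xyz))))
    stop_classed("non-finite backbone coordinates", "degenerate_geometry")
  v1 <- ca_xyz - n_xyz
  if (vnorm(v1) < 0.5)
    stop_classed("degenerate backbone geometry: |CA-N| < 0.5 A", "degenerate_geometry")
  cr <- cross3(v1, c_xyz - ca_xyz)
  if (vnorm(cr) < 1e-6)
    stop_classed("degenerate backbone geometry: N, CA, C collinear", "degenerate_geometry")
  e_x <- v1 / vnorm(v1)
  e_y <- cr / vnorm(cr)
  e_z <- cross3(e_x, e_y)
  list(origin = ca_xyz, e_x = e_x, e_y = e_y, e_z = e_z)
}

#' Read a frame-aligned side-chain library
#'
#' The library lists side-chain heavy atoms per residue type and conformer,
#' with coordinates already expressed in the canonical backbone frame. The
#' bundled file holds ideal (synthetic) side-chain geometries with chi1
#' variants; an external library in the same tabular format can be supplied
#' to reproduce other masks.
#'
#' @param path Path to a tab-separated library file; default the bundled one.
#' @return Data frame with columns `restype`, `rotamer`, `atom`, `element`,
#'   `x`, `y`, `z`.
#' @export
read_sidechain_library <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "ideal_sidechains.tsv", package = "mapseqid",
                        mustWork = TRUE)
  lib <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                           stringsAsFactors = FALSE)
  need <- c("restype", "rotamer", "atom", "element", "x", "y", "z")
  if (!all(need %in% names(lib)))
    stop_classed("side-chain library must have columns restype/rotamer/atom/element/x/y/z",
                 "format_error")
  if (nrow(lib) == 0) stop_classed("empty side-chain library", "format_error")
  lib
}

#' Build the side-chain grid mask
#'
#' Candidate points are integer multiples of `spacing` inside the bounding box
#' of all library side-chain atoms padded by `inclusion_radius`; a point is
#' kept iff its distance to the nearest side-chain atom (any type, any
#' conformer) is at most `inclusion_radius`. Offsets are returned in a
#' deterministic lexicographic order.
#'
#' @param library Side-chain library data frame (see [read_sidechain_library]).
#' @param spacing Lattice spacing in Angstrom (default 1.0).
#' @param inclusion_radius Inclusion radius in Angstrom (default 1.0).
#' @return Object of class `grid_mask`: integer `offsets` (n x 3, spacing
#'   units), `spacing`, `inclusion_radius`, `n_points`.
#' @export
build_grid_mask <- function(library, spacing = 1.0, inclusion_radius = 1.0) {
  if (is.null(library) || nrow(library) == 0)
    stop_classed("empty side-chain library", "format_error")
  at <- as.matrix(library[, c("x", "y", "z")])
  lo <- floor((apply(at, 2, min) - inclusion_radius) / spacing)
  hi <- ceiling((apply(at, 2, max) + inclusion_radius) / spacing)
  cand <- as.matrix(expand.grid(i = lo[1]:hi[1], j = lo[2]:hi[2], k = lo[3]:hi[3]))
  pts <- cand * spacing
  # min distance to any atom, blockwise to bound memory
  keep <- logical(nrow(pts))
  r2 <- inclusion_radius^2
  blk <- 4096L
  for (s in seq(1L, nrow(pts), by = blk)) {
    e <- min(s + blk - 1L, nrow(pts))
    d2 <- outer(rowSums(pts[s:e, , drop = FALSE]^2), rowSums(at^2), "+") -
      2 * pts[s:e, , drop = FALSE] %*% t(at)
    keep[s:e] <- apply(d2, 1, min) <= r2 + 1e-9
  }
  off <- cand[keep, , drop = FALSE]
  off <- off[order(off[, 1], off[, 2], off[, 3]), , drop = FALSE]
  storage.mode(off) <- "integer"
  dimnames(off) <- NULL
  structure(list(offsets = off, spacing = spacing,
                 inclusion_radius = inclusion_radius, n_points = nrow(off)),
            class = "grid_mask")
}

#' @export
print.grid_mask <- function(x, ...) {
  cat(sprintf("grid_mask: %d points, %.2f A spacing, %.2f A inclusion radius\n",
              x$n_points, x$spacing, x$inclusion_radius))
  invisible(x)
}

#' Extract the masked-grid density descriptor of one residue
#'
#' Samples (trilinear interpolation) the map at `origin + spacing * (i e_x +
#' j e_y + k e_z)` for every mask offset, standardizing values with the
#' supplied normalizer. Residues whose sampling points fall outside a
#' non-periodic map yield `NULL` (flagged; callers skip and report them).
#'
#' @param map A [density_map].
#' @param frame Local frame from [build_local_frame].
#' @param mask Grid mask from [build_grid_mask].
#' @param normalizer List with `mean` and `sd` (see [map_normalizer]), or
#'   `NULL` for raw values.
#' @return Numeric vector of length `mask$n_points`, or `NULL` if the residue
#'   could not be sampled.
#' @export
extract_descriptor <- function(map, frame, mask, normalizer = NULL) {
  R <- cbind(frame$e_x, frame$e_y, frame$e_z)
  pts <- mask$offsets %*% t(R) * mask$spacing
  pts <- sweep(pts, 2, frame$origin, "+")
  vals <- tryCatch(interpolate_density(map, pts),
                   out_of_bounds = function(e) NULL)
  if (is.null(vals)) return(NULL)
  if (!is.null(normalizer)) vals <- (vals - normalizer$mean) / normalizer$sd
  if (any(!is.finite(vals))) return(NULL)
  vals
}
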
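# MRC/CCP4 density-map container and I/O.
#
# The on-disk format is MRC2014 (mode 2, float32). Only orthogonal cells
# (alpha = beta = gamma = 90 deg) are supported; the axis order declared in
# the header (MAPC/MAPR/MAPS) is normalized to a canonical X,Y,Z layout on
# read. Internally all coordinates are orthogonal Angstroms; grid indices are
# 0-based with half-open voxel intervals.

#' Construct a density map
#'
#' @param values 3D numeric array of density values, indexed `[x, y, z]`.
#' @param voxel_size Voxel edge lengths in Angstrom (length 1 or 3, all > 0).
#' @param origin Orthogonal Angstrom coordinates of grid point (0, 0, 0).
#' @param periodic Logical; if `TRUE` the grid is treated as a full unit cell
#'   and sampling wraps around (crystallographic maps). Cryo-EM reconstructions
#'   are non-periodic and out-of-bounds sampling raises an error.
#' @return An object of class `density_map`.
#' @export
density_map <- function(values, voxel_size, origin = c(0, 0, 0), periodic = FALSE) {
  if (length(dim(values)) != 3L)
    stop_classed("'values' must be a 3D array", "format_error")
  if (any(dim(values) < 2L))
    stop_classed("grid must have at least 2 points per axis", "format_error")
  voxel_size <- rep_len(as.numeric(voxel_size), 3L)
  if (any(!is.finite(voxel_size)) || any(voxel_size <= 0))
    stop_classed("voxel_size must be positive and finite", "format_error")
  origin <- as.numeric(origin)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop_classed("origin must be 3 finite coordinates", "format_error")
  structure(list(values = values, voxel_size = voxel_size, origin = origin,
                 periodic = isTRUE(periodic)),
            class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("density_map: %d x %d x %d voxels, voxel %.3f x %.3f x %.3f A%s\n",
              d[1], d[2], d[3], x$voxel_size[1], x$voxel_size[2], x$voxel_size[3],
              if (x$periodic) " (periodic)" else ""))
  cat(sprintf("  origin (%.2f, %.2f, %.2f) A; density range [%.3g, %.3g]\n",
              x$origin[1], x$origin[2], x$origin[3],
              min(x$values), max(x$values)))
  invisible(x)
}

#' Read an MRC/CCP4 density map
#'
#' Reads a mode-2 (float32) MRC2014 volume, permuting the stored axis order
#' (header words MAPC/MAPR/MAPS) into the canonical X,Y,Z layout so that the
#' same orthogonal coordinate addresses the same density regardless of how the
#' file was laid out. The map origin is taken from the ORIGIN header record
#' when set, otherwise from NCSTART/NRSTART/NSSTART times the voxel size.
#'
#' @param path Path to the map file.
#' @param periodic `NULL` (auto-detect: periodic iff the grid covers the full
#'   unit cell and the space group is > 1) or a logical override.
#' @return A [density_map].
#' @export
read_density_map <- function(path, periodic = NULL) {
  if (!file.exists(path))
    stop_classed(sprintf("map file not found: %s", path), "format_error")
  sz <- file.size(path)
  if (is.na(sz) || sz < 1024)
    stop_classed(sprintf("not a valid MRC file (size %d < 1024-byte header): %s", sz, path),
                 "format_error")
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_int <- readBin(con, "integer", n = 256, size = 4, endian = "little")
  seek(con, 0)
  hdr_dbl <- readBin(con, "numeric", n = 256, size = 4, endian = "little")
  nxyz <- hdr_int[1:3]
  mode <- hdr_int[4]
  nstart <- hdr_int[5:7]
  mxyz <- hdr_int[8:10]
  cella <- hdr_dbl[11:13]
  cellb <- hdr_dbl[14:16]
  mapcrs <- hdr_int[17:19]
  ispg <- hdr_int[23]
  nsymbt <- hdr_int[24]
  org <- hdr_dbl[50:52]
  if (mode != 2L)
    stop_classed(sprintf("unsupported MRC MODE %d (only mode 2, float32)", mode),
                 "format_error")
  if (any(nxyz < 2L) || any(mxyz < 1L))
    stop_classed(sprintf("invalid MRC grid dimensions NX/NY/NZ = %s", paste(nxyz, collapse = "x")),
                 "format_error")
  if (any(abs(cellb - 90) > 1e-3))
    stop_classed(sprintf("non-orthogonal cell (angles %s) not supported",
                         paste(round(cellb, 2), collapse = "/")), "format_error")
  if (!setequal(mapcrs, 1:3))
    stop_classed(sprintf("invalid MAPC/MAPR/MAPS axis order %s", paste(mapcrs, collapse = ",")),
                 "format_error")
  n_total <- prod(nxyz)
  if (sz < 1024 + nsymbt + 4 * n_total)
    stop_classed(sprintf("truncated MRC file: NX*NY*NZ = %d values expected", n_total),
                 "format_error")
  seek(con, 1024 + nsymbt)
  vals <- readBin(con, "numeric", n = n_total, size = 4, endian = "little")
  arr <- array(vals, dim = nxyz)          # dims follow file order (MAPC fastest)
  perm <- match(1:3, mapcrs)
  arr <- aperm(arr, perm)                 # canonical [x, y, z]
  nxyz_c <- nxyz[perm]
  nstart_c <- nstart[perm]
  # per crystal axis: voxel size = cell edge / sampling
  voxel <- cella / mxyz
  origin <- if (any(org != 0)) org else nstart_c * voxel
  if (is.null(periodic)) {
    periodic <- ispg > 1L && all(nxyz[perm] == mxyz)
  }
  density_map(arr, voxel, origin, periodic = periodic)
}

#' Write a density map in MRC2014 format
#'
#' @param map A [density_map].
#' @param path Output path.
#' @param axis_order Integer permutation of 1:3 giving the crystal axes stored
#'   fastest-to-slowest (MAPC, MAPR, MAPS). Default canonical X,Y,Z.
#' @param ispg Space-group number to record (default 1).
#' @return `path`, invisibly.
#' @export
write_density_map <- function(map, path, axis_order = 1:3, ispg = 1L) {
  stopifnot(inherits(map, "density_map"), setequal(axis_order, 1:3))
  d <- dim(map$values)
  arr <- aperm(map$values, axis_order)   # stored dims follow axis_order
  hdr_i <- integer(256)
  hdr_d <- numeric(256)
  use_d <- logical(256)
  hdr_i[1:3] <- d[axis_order]
  hdr_i[4] <- 2L
  hdr_i[5:7] <- 0L
  hdr_i[8:10] <- d
  hdr_d[11:13] <- d * map$voxel_size; use_d[11:13] <- TRUE
  hdr_d[14:16] <- 90; use_d[14:16] <- TRUE
  hdr_i[17:19] <- as.integer(axis_order)
  hdr_d[20] <- min(map$values); hdr_d[21] <- max(map$values)
  hdr_d[22] <- mean(map$values); use_d[20:22] <- TRUE
  hdr_i[23] <- as.integer(ispg)
  hdr_i[24] <- 0L
  hdr_d[50:52] <- map$origin; use_d[50:52] <- TRUE
  hdr_i[53] <- readBin(charToRaw("MAP "), "integer", size = 4, endian = "little")
  hdr_i[54] <- readBin(as.raw(c(0x44, 0x41, 0x00, 0x00)), "integer", size = 4,
                       endian = "little")
  hdr_d[55] <- stats::sd(map$values); use_d[55] <- TRUE
  hdr_i[56] <- 0L
  con <- file(path, "wb")
  on.exit(close(con))
  for (w in 1:256) {
    if (use_d[w]) writeBin(hdr_d[w], con, size = 4, endian = "little")
    else writeBin(as.integer(hdr_i[w]), con, size = 4, endian = "little")
  }
  writeBin(as.vector(arr), con, size = 4, endian = "little")
  invisible(path)
}

#' Trilinear density interpolation
#'
#' Interpolates map density at arbitrary orthogonal coordinates from the 8
#' surrounding voxels. For periodic (unit-cell) maps sampling wraps around;
#' for non-periodic maps points outside the grid raise an out-of-bounds error.
#'
#' @param map A [density_map].
#' @param points Numeric matrix (n x 3) or length-3 vector of orthogonal
#'   Angstrom coordinates.
#' @return Numeric vector of n interpolated density values.
#' @export
interpolate_density <- function(map, points) {
  stopifnot(inherits(map, "density_map"))
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  storage.mode(points) <- "double"
  d <- dim(map$values)
  f <- sweep(sweep(points, 2, map$origin), 2, map$voxel_size, "/")
  i0 <- floor(f)
  t <- f - i0
  if (map$periodic) {
    idx_lo <- sweep(i0, 2, d, function(i, n) ((i %% n) + n) %% n)
    idx_hi <- sweep(idx_lo + 1, 2, d, "%%")
  } else {
    # allow points exactly on the upper face (within float tolerance)
    hi_edge <- sweep(f, 2, d - 1, function(x, m) x >= m & x <= m + 1e-9)
    i0[hi_edge] <- rep(d - 2, each = nrow(points))[hi_edge]
    t <- f - i0
    if (any(i0 < 0) || any(sweep(i0, 2, d - 2, ">")))
      stop_classed("point outside non-periodic map bounds", "out_of_bounds")
    idx_lo <- i0
    idx_hi <- i0 + 1
  }
  nx <- d[1]; nxy <- d[1] * d[2]
  lin <- function(ix, iy, iz) 1 + ix + nx * iy + nxy * iz
  v <- map$values
  tx <- t[, 1]; ty <- t[, 2]; tz <- t[, 3]
  v[lin(idx_lo[, 1], idx_lo[, 2], idx_lo[, 3])] * (1 - tx) * (1 - ty) * (1 - tz) +
  v[lin(idx_hi[, 1], idx_lo[, 2], idx_lo[, 3])] * tx       * (1 - ty) * (1 - tz) +
  v[lin(idx_lo[, 1], idx_hi[, 2], idx_lo[, 3])] * (1 - tx) * ty       * (1 - tz) +
  v[lin(idx_hi[, 1], idx_hi[, 2], idx_lo[, 3])] * tx       * ty       * (1 - tz) +
  v[lin(idx_lo[, 1], idx_lo[, 2], idx_hi[, 3])] * (1 - tx) * (1 - ty) * tz +
  v[lin(idx_hi[, 1], idx_lo[, 2], idx_hi[, 3])] * tx       * (1 - ty) * tz +
  v[lin(idx_lo[, 1], idx_hi[, 2], idx_hi[, 3])] * (1 - tx) * ty       * tz +
  v[lin(idx_hi[, 1], idx_hi[, 2], idx_hi[, 3])] * tx       * ty       * tz
}

#' Local map normalization statistics
#'
#' Mean and standard deviation of map density over voxels within `radius`
#' Angstrom of the supplied atom positions (typically the model backbone).
#' Descriptors are standardized with these statistics so that maps of
#' arbitrary absolute scale produce comparable classifier inputs.
#'
#' @param map A [density_map].
#' @param atoms_xyz Numeric matrix (n x 3) of atom coordinates in Angstrom.
#' @param radius Inclusion radius in Angstrom (default 3).
#' @return List with elements `mean` and `sd`.
#' @export
map_normalizer <- function(map, atoms_xyz, radius = 3) {
  stopifnot(inherits(map, "density_map"))
  if (is.null(dim(atoms_xyz))) atoms_xyz <- matrix(atoms_xyz, ncol = 3)
  d <- dim(map$values)
  vx <- map$voxel_size
  sel <- vector("list", nrow(atoms_xyz))
  for (i in seq_len(nrow(atoms_xyz))) {
    f <- (atoms_xyz[i, ] - map$origin) / vx
    lo <- pmax(ceiling(f - radius / vx), 0)
    hi <- pmin(floor(f + radius / vx), d - 1)
    if (any(lo > hi)) next
    ix <- lo[1]:hi[1]; iy <- lo[2]:hi[2]; iz <- lo[3]:hi[3]
    g <- expand.grid(ix = ix, iy = iy, iz = iz)
    dist2 <- ((g$ix - f[1]) * vx[1])^2 + ((g$iy - f[2]) * vx[2])^2 +
             ((g$iz - f[3]) * vx[3])^2
    keep <- dist2 <= radius^2
    sel[[i]] <- 1 + g$ix[keep] + d[1] * g$iy[keep] + d[1] * d[2] * g$iz[keep]
  }
  ind <- unique(unlist(sel))
  if (length(ind) < 2)
    stop_classed("no map voxels within radius of the supplied atoms", "out_of_bounds")
  vals <- map$values[ind]
  s <- stats::sd(vals)
  if (!is.finite(s) || s == 0) s <- 1
  list(mean = mean(vals), sd = s)
}
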
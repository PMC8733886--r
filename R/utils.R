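# Shared constants and small helpers.

#' The 20-letter amino-acid alphabet, alphabetically ordered
#'
#' Order is fixed package-wide: probability vectors, classifier outputs and
#' MSA column counts all index residue types in this order.
#'
#' @return Character vector of the 20 one-letter codes.
#' @export
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

AA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
        "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

AA3 <- c(A = "ALA", C = "CYS", D = "ASP", E = "GLU", F = "PHE", G = "GLY",
         H = "HIS", I = "ILE", K = "LYS", L = "LEU", M = "MET", N = "ASN",
         P = "PRO", Q = "GLN", R = "ARG", S = "SER", T = "THR", V = "VAL",
         W = "TRP", Y = "TYR")

AA1 <- structure(names(AA3), names = AA3)

# Ambiguity codes mapped to the nearest standard type; 'X' is handled as a
# background wildcard at scoring time and is deliberately absent here.
AA_AMBIG <- c(B = "N", Z = "Q", U = "C", O = "K")

#' @keywords internal
stop_classed <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "mapseqid_error")))
}

# Map sequence letters to indices in AA; ambiguity codes folded to their
# nearest standard type, 'X' (and anything else unknown) to NA.
seq_to_idx <- function(s) {
  letters1 <- strsplit(toupper(s), "")[[1]]
  known <- !is.na(match(letters1, names(AA_AMBIG)))
  letters1[known] <- AA_AMBIG[letters1[known]]
  match(letters1, AA)
}

vnorm <- function(v) sqrt(sum(v * v))

unit3 <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop_classed("cannot normalize zero-length vector", "degenerate_geometry")
  v / n
}

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

# Uniform random rotation matrix (quaternion method).
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         nrow = 3, byrow = TRUE)
}
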
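#' Signed dihedral angle of four points
#'
#' IUPAC sign convention (right-hand rule looking down the central bond),
#' reported in degrees in the half-open range (-180, 180].
#'
#' @param p1,p2,p3,p4 Numeric length-3 coordinate vectors (Angstrom).
#' @return Angle in degrees.
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- .cross3(b1, b2)
  n2 <- .cross3(b2, b3)
  b2hat <- b2 / sqrt(sum(b2^2))
  x <- sum(n1 * n2)
  y <- sum(.cross3(n1, n2) * b2hat)
  ang <- atan2(y, x) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Shortest distance between two atom sets
#'
#' Exact minimum over the full cross-product of the two coordinate sets, with
#' ties broken by first occurrence in input order (set A scanned first).
#'
#' @param set_a,set_b Coordinate tibbles (columns `x`, `y`, `z`, optionally
#'   `atom_name`) or numeric matrices with 3 columns.
#' @return List with `distance` (Angstrom), indices `idx_a`, `idx_b` of the
#'   achieving pair, and `atom_a`/`atom_b` names when available.
#' @export
min_distance <- function(set_a, set_b) {
  a <- if (is.matrix(set_a)) set_a else atom_xyz(set_a)
  b <- if (is.matrix(set_b)) set_b else atom_xyz(set_b)
  if (nrow(a) == 0 || nrow(b) == 0) {
    stop_input("min_distance requires two non-empty coordinate sets")
  }
  # squared cross-distance matrix, rows = A
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  # scan A-major so ties resolve to the earliest A (then earliest B) atom
  k <- which.min(t(d2))
  nb <- nrow(b)
  ia <- (k - 1L) %/% nb + 1L
  ib <- (k - 1L) %% nb + 1L
  name_of <- function(s, i) {
    if (!is.matrix(s) && "atom_name" %in% names(s)) s$atom_name[i] else NA_character_
  }
  list(distance = sqrt(d2[ia, ib]),
       idx_a = ia, idx_b = ib,
       atom_a = name_of(set_a, ia), atom_b = name_of(set_b, ib))
}
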
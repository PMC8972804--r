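# Pure geometric kernels.  All angles are in degrees; distances in Angstrom.
# Sign convention for torsions is the IUPAC one (right-handed rotation of the
# p1-p2 bond onto the p3-p4 bond, viewed down p2->p3, is positive).

DEG <- 180 / pi

.check_finite <- function(...) {
  for (v in list(...)) {
    if (!is.numeric(v) || length(v) != 3L || any(!is.finite(v)))
      stop("coordinates must be finite numeric 3-vectors", call. = FALSE)
  }
  invisible(TRUE)
}

#' Euclidean distance between two points
#'
#' @param p,q Numeric 3-vectors (Angstrom).
#' @return Distance in Angstrom.
#' @export
atom_distance <- function(p, q) {
  .check_finite(p, q)
  sqrt(sum((p - q)^2))
}

#' Included angle at a vertex
#'
#' Angle a-vertex-c in degrees, in `[0, 180]`.  Errors on a degenerate
#' (zero-length) arm.
#'
#' @param a,vertex,c Numeric 3-vectors.
#' @return Angle in degrees.
#' @export
bond_angle <- function(a, vertex, c) {
  .check_finite(a, vertex, c)
  u <- a - vertex
  v <- c - vertex
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu < 1e-6 || nv < 1e-6)
    stop("degenerate angle: zero-length arm", call. = FALSE)
  cosang <- sum(u * v) / (nu * nv)
  cosang <- min(1, max(-1, cosang))
  acos(cosang) * DEG
}

#' Signed torsion angle about the p2-p3 axis
#'
#' IUPAC-signed dihedral in `(-180, 180]`.  A cis arrangement gives 0, trans
#' gives 180.  Satisfies `torsion_angle(p4,p3,p2,p1) == torsion_angle(p1,p2,p3,p4)`
#' and negates under mirror reflection.
#'
#' @param p1,p2,p3,p4 Numeric 3-vectors.
#' @return Angle in degrees.
#' @export
torsion_angle <- function(p1, p2, p3, p4) {
  .check_finite(p1, p2, p3, p4)
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- .cross3(b1, b2)
  n2 <- .cross3(b2, b3)
  if (sum(n1^2) < 1e-12 || sum(n2^2) < 1e-12)
    stop("degenerate dihedral: collinear points", call. = FALSE)
  m1 <- .cross3(n1, b2 / sqrt(sum(b2^2)))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  ang <- atan2(y, x) * DEG
  if (ang <= -180) ang <- ang + 360
  ang
}

.cross3 <- function(u, v) {
  c(u[2L] * v[3L] - u[3L] * v[2L],
    u[3L] * v[1L] - u[1L] * v[3L],
    u[1L] * v[2L] - u[2L] * v[1L])
}

#' Circular mean and standard deviation
#'
#' Mean direction and circular SD (both degrees) of a sample of angles, so a
#' sample straddling +/-180 is handled correctly.  For a tight cluster far
#' from the wrap point this agrees with the linear mean/SD.  The mean is
#' reported in `(-180, 180]`.
#'
#' @param values Numeric vector of angles in degrees, length >= 2.
#' @return Named numeric vector `c(mean=, sd=)`.
#' @export
circular_mean_sd <- function(values) {
  if (length(values) < 2L || any(!is.finite(values)))
    stop("need >= 2 finite angle values", call. = FALSE)
  rad <- values / DEG
  s <- mean(sin(rad)); cc <- mean(cos(rad))
  R <- sqrt(s^2 + cc^2)
  if (R < 1e-8)
    stop("circular mean undefined: resultant length ~ 0", call. = FALSE)
  m <- atan2(s, cc) * DEG
  if (m <= -180) m <- m + 360
  sdv <- sqrt(pmax(0, -2 * log(R))) * DEG
  c(mean = m, sd = sdv)
}

#' Smallest absolute difference between two angles
#'
#' @param x,y Angles in degrees (vectorized).
#' @return Difference in degrees, in `[0, 180]`.
#' @export
angular_difference <- function(x, y) {
  d <- (x - y) %% 360
  pmin(d, 360 - d)
}

# Vectorized row-wise kernels over n x 3 coordinate matrices.  NA rows
# propagate to NA results (used for missing atoms/neighbors).
.row_norm <- function(m) sqrt(rowSums(m^2))

.row_dist <- function(a, b) .row_norm(a - b)

.row_angle <- function(a, v, cc) {
  u <- a - v
  w <- cc - v
  nu <- .row_norm(u); nw <- .row_norm(w)
  cosang <- rowSums(u * w) / (nu * nw)
  cosang[nu < 1e-6 | nw < 1e-6] <- NA_real_
  cosang <- pmin(1, pmax(-1, cosang))
  acos(cosang) * DEG
}

.row_cross <- function(u, v) {
  cbind(u[, 2L] * v[, 3L] - u[, 3L] * v[, 2L],
        u[, 3L] * v[, 1L] - u[, 1L] * v[, 3L],
        u[, 1L] * v[, 2L] - u[, 2L] * v[, 1L])
}

.row_dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- .row_cross(b1, b2)
  n2 <- .row_cross(b2, b3)
  bad <- rowSums(n1^2) < 1e-12 | rowSums(n2^2) < 1e-12
  b2u <- b2 / .row_norm(b2)
  m1 <- .row_cross(n1, b2u)
  ang <- atan2(rowSums(m1 * n2), rowSums(n1 * n2)) * DEG
  ang[bad] <- NA_real_
  ang[!is.na(ang) & ang <= -180] <- ang[!is.na(ang) & ang <= -180] + 360
  ang
}
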
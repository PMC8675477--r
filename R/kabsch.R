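# Rigid-body least-squares superposition.

#' Kabsch superposition
#'
#' Finds the proper rotation `R` and translation `t` minimising the RMSD of
#' `coords_a` onto `coords_b` (column-vector convention: a point `x` maps to
#' `R x + t`). Reflections are rejected by the usual determinant correction,
#' so `R` is always a proper rotation (det +1).
#'
#' @param coords_a,coords_b Numeric n x 3 matrices of paired points (n >= 3,
#'   not all collinear).
#' @return Object of class `"superposition"`: `rotation` (3 x 3),
#'   `translation` (length 3), `rmsd` (Angstrom).
#' @export
kabsch <- function(coords_a, coords_b) {
  a <- as.matrix(coords_a); b <- as.matrix(coords_b)
  if (nrow(a) != nrow(b)) stop("coordinate sets must have equal length")
  if (nrow(a) < 3L) stop("at least 3 points are required")
  if (ncol(a) != 3L || ncol(b) != 3L) stop("coordinates must be n x 3")
  if (!all(is.finite(a)) || !all(is.finite(b))) stop("non-finite coordinates")
  ca <- colMeans(a); cb <- colMeans(b)
  ac <- sweep(a, 2, ca); bc <- sweep(b, 2, cb)
  # collinear (or coincident) point sets leave the rotation underdetermined
  da <- svd(ac, nu = 0, nv = 0)$d
  db <- svd(bc, nu = 0, nv = 0)$d
  if (da[2] < 1e-8 * max(1, da[1]) || db[2] < 1e-8 * max(1, db[1]))
    stop("degenerate geometry: points are collinear")
  h <- crossprod(ac, bc)             # sum of a_i b_i^T
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  r <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  tv <- cb - as.numeric(r %*% ca)
  moved <- apply_superposition(list(rotation = r, translation = tv), a)
  rmsd <- sqrt(mean(rowSums((moved - b)^2)))
  structure(list(rotation = r, translation = tv, rmsd = rmsd),
            class = "superposition")
}

#' Apply a superposition to coordinates
#' @param sup A `"superposition"` (or list with `rotation`, `translation`).
#' @param coords Numeric n x 3 matrix.
#' @return Transformed n x 3 matrix.
#' @export
apply_superposition <- function(sup, coords) {
  sweep(as.matrix(coords) %*% t(sup$rotation), 2, sup$translation, "+")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("<superposition> rmsd = %.4f A, rotation angle = %.2f deg\n",
              x$rmsd, rotation_angle_deg(x$rotation)))
  invisible(x)
}

rotation_angle_deg <- function(r) {
  acos(max(-1, min(1, (sum(diag(r)) - 1) / 2))) * 180 / pi
}

# Rotation of angle theta (radians) about unit axis u (Rodrigues formula).
rotation_about_axis <- function(u, theta) {
  u <- u / sqrt(sum(u^2))
  ux <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) * cos(theta) + sin(theta) * ux + (1 - cos(theta)) * tcrossprod(u)
}

# Minimal rotation mapping unit vector a onto unit vector b.
rotation_between <- function(a, b) {
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  v <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  s <- sqrt(sum(v^2)); cth <- sum(a * b)
  if (s < 1e-12) {
    if (cth > 0) return(diag(3))
    # antiparallel: rotate pi about any axis perpendicular to a
    p <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    w <- p - sum(p * a) * a
    return(rotation_about_axis(w, pi))
  }
  rotation_about_axis(v / s, atan2(s, cth))
}
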
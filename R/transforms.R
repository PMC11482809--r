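# Rigid transforms, screw-axis decomposition and least-squares superposition.
# Conventions: coordinates in Angstrom, angles in degrees at the user surface
# (radians internally); transforms act as x' = R x + t on column points.

.deg2rad <- function(x) x * pi / 180
.rad2deg <- function(x) x * 180 / pi

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Construct a rigid transform
#'
#' A rigid (proper) transform is a rotation plus a translation,
#' `x' = R x + t`. The rotation must be orthonormal with determinant +1
#' (tolerance 1e-9).
#'
#' @param rotation 3x3 proper orthonormal matrix (dimensionless).
#' @param translation numeric length-3 translation vector (Angstrom).
#' @return An object of class `rigid_transform` with elements `rotation`
#'   and `translation`.
#' @examples
#' rigid_transform(diag(3), c(0, 0, 27))
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- unname(as.matrix(rotation))
  translation <- unname(as.numeric(translation))
  stopifnot(identical(dim(rotation), c(3L, 3L)), length(translation) == 3L)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9)
    stop("rotation is not orthonormal (tolerance 1e-9)")
  if (abs(det(rotation) - 1) > 1e-9)
    stop("rotation must be proper (determinant +1)")
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  s <- screw_decompose(x)
  cat(sprintf("<rigid_transform> twist %.4f deg, rise %.4f A about axis (%.3f, %.3f, %.3f)\n",
              s$twist, s$rise, s$axis[1], s$axis[2], s$axis[3]))
  invisible(x)
}

#' Compose two rigid transforms
#'
#' Returns `a` composed after `b`: applying the result is applying `b`,
#' then `a`.
#'
#' @param a,b `rigid_transform` objects.
#' @return A `rigid_transform`.
#' @export
compose_transform <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  as.numeric(a$rotation %*% b$translation) + a$translation)
}

#' Invert a rigid transform
#' @param x A `rigid_transform`.
#' @return The inverse `rigid_transform`.
#' @export
invert_transform <- function(x) {
  rt <- t(x$rotation)
  rigid_transform(rt, -as.numeric(rt %*% x$translation))
}

#' Apply a rigid transform to coordinates
#'
#' @param x A `rigid_transform`.
#' @param coords numeric matrix, one 3D point per row (Angstrom). Row names
#'   (point labels) are preserved.
#' @return Transformed coordinate matrix of the same shape.
#' @export
apply_transform <- function(x, coords) {
  coords <- rbind(coords)
  out <- coords %*% t(x$rotation)
  out <- sweep(out, 2, x$translation, "+")
  rownames(out) <- rownames(coords)
  out
}

#' Rotation matrix about an arbitrary axis
#'
#' Rodrigues rotation by `angle` degrees (right-hand rule) about the unit
#' direction `axis`.
#'
#' @param axis numeric length-3 direction (normalized internally).
#' @param angle rotation angle in degrees.
#' @return 3x3 rotation matrix.
#' @export
rotation_about_axis <- function(axis, angle) {
  n <- as.numeric(axis)
  nn <- sqrt(sum(n^2))
  if (nn < 1e-12) stop("axis has zero length")
  n <- n / nn
  th <- .deg2rad(angle)
  K <- matrix(c(0, n[3], -n[2],
                -n[3], 0, n[1],
                n[2], -n[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Build a screw transform from helical parameters
#'
#' The screw advances by `rise` Angstrom along `axis` while rotating by
#' `twist` degrees about the axis line passing through `axis_point`.
#' This is the inverse of [screw_decompose()].
#'
#' @param twist rotation angle in degrees (right-hand rule about `axis`).
#' @param rise translation along `axis` in Angstrom.
#' @param axis unit 3-vector screw axis direction.
#' @param axis_point a point on the screw axis (Angstrom).
#' @return A `rigid_transform`.
#' @examples
#' screw_transform(-167, 27)  # canonical F-actin 1-start step
#' @export
screw_transform <- function(twist, rise, axis = c(0, 0, 1),
                            axis_point = c(0, 0, 0)) {
  axis <- as.numeric(axis); axis <- axis / sqrt(sum(axis^2))
  R <- rotation_about_axis(axis, twist)
  t <- rise * axis + as.numeric((diag(3) - R) %*% axis_point)
  rigid_transform(R, t)
}

#' Screw-axis decomposition of a rigid transform
#'
#' Decomposes a rigid transform into its Chasles screw form: a signed
#' rotation `twist` (degrees, right-hand rule) about a unique axis line,
#' plus a translation `rise` (Angstrom) along that axis. For inter-subunit
#' transforms of a helical polymer these are the local helical twist and
#' rise.
#'
#' Sign conventions: the axis is chosen so that `rise >= 0`; when the rise
#' is zero the axis is chosen so that `twist >= 0` (so `twist` lies in
#' `(-180, 180]`). A twist within 1e-6 degrees of 180 is reported as +180.
#' The identity transform returns twist 0, rise 0 and, by convention,
#' axis `+z`.
#'
#' @param transform A `rigid_transform`.
#' @return A list with `twist` (degrees), `rise` (Angstrom), `axis` (unit
#'   3-vector) and `axis_point` (a point on the axis, the one closest to
#'   the origin).
#' @seealso [screw_transform()] for the inverse operation.
#' @examples
#' s <- screw_decompose(screw_transform(-167, 27))
#' c(s$twist, s$rise)
#' @export
screw_decompose <- function(transform) {
  R <- transform$rotation
  t <- transform$translation
  tol <- 1e-9

  cosang <- (sum(diag(R)) - 1) / 2
  cosang <- max(-1, min(1, cosang))
  ang <- acos(cosang)  # [0, pi]

  if (ang < 1e-9) {
    # pure translation (or identity)
    d <- sqrt(sum(t^2))
    if (d < tol)
      return(list(twist = 0, rise = 0, axis = c(0, 0, 1),
                  axis_point = c(0, 0, 0)))
    return(list(twist = 0, rise = d, axis = t / d, axis_point = c(0, 0, 0)))
  }

  if (pi - ang < 1e-7) {
    # 180-degree rotation: axis from the symmetric part, R + I = 2 n n^T
    B <- R + diag(3)
    j <- which.max(colSums(B^2))
    axis <- B[, j] / sqrt(sum(B[, j]^2))
    twist <- 180
    rise <- sum(t * axis)
    if (rise < -tol) {
      axis <- -axis
      rise <- -rise
    }
    if (abs(rise) <= tol) rise <- 0
  } else {
    axis <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) /
      (2 * sin(ang))
    twist <- .rad2deg(ang)
    rise <- sum(t * axis)
    if (rise < -tol) {
      axis <- -axis
      twist <- -twist
      rise <- -rise
    } else if (abs(rise) <= tol) {
      rise <- 0
      if (twist < 0) {
        axis <- -axis
        twist <- -twist
      }
    }
  }
  if (abs(twist - 180) < 1e-6) twist <- 180

  # point on the axis closest to the origin: solve (I - R) p = t_perp
  t_perp <- t - sum(t * axis) * axis
  th <- .deg2rad(twist)
  if (abs(sin(th / 2)) < 1e-12) {
    axis_point <- c(0, 0, 0)
  } else {
    axis_point <- 0.5 * (t_perp + .cross3(axis, t_perp) / tan(th / 2))
    axis_point <- axis_point - sum(axis_point * axis) * axis
  }

  list(twist = twist, rise = rise, axis = axis, axis_point = axis_point)
}

#' Kabsch least-squares superposition
#'
#' Finds the rigid transform minimizing the RMSD between two order-matched
#' point sets, mapping `a` onto `b`.
#'
#' @param a,b numeric matrices of matched 3D points (rows), same dimensions.
#' @return A list with `transform` (`rigid_transform` mapping a onto b) and
#'   `rmsd` (Angstrom, after superposition).
#' @keywords internal
kabsch <- function(a, b) {
  a <- rbind(a); b <- rbind(b)
  stopifnot(nrow(a) == nrow(b), ncol(a) == 3, ncol(b) == 3, nrow(a) >= 3)
  ca <- colMeans(a); cb <- colMeans(b)
  A <- sweep(a, 2, ca); B <- sweep(b, 2, cb)
  H <- crossprod(A, B)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  # guard tiny numerical drift off the orthogonal group
  if (max(abs(crossprod(R) - diag(3))) > 1e-12) {
    sr <- svd(R); R <- sr$u %*% t(sr$v)
  }
  tr <- cb - as.numeric(R %*% ca)
  tf <- rigid_transform(R, tr)
  dev <- apply_transform(tf, a) - b
  list(transform = tf, rmsd = sqrt(mean(rowSums(dev^2))))
}

#' Superpose two labeled point sets and report the RMSD
#'
#' Least-squares (Kabsch) superposition of labeled coordinate sets, e.g.
#' C-alpha traces of two structures. Points are matched by the intersection
#' of their labels (matrix row names, typically residue identifiers); only
#' labels present in both sets are used and the count used is reported. No
#' outlier rejection is performed.
#'
#' @param coords_a,coords_b numeric matrices of 3D points with row-name
#'   labels (Angstrom). Unlabeled matrices of equal size are matched by row
#'   order.
#' @return A list with `rmsd` (Angstrom), `transform` (the
#'   `rigid_transform` mapping `coords_a` onto `coords_b`) and `n_used`
#'   (number of matched points).
#' @examples
#' a <- matrix(rnorm(30), 10, 3, dimnames = list(paste0("R", 1:10), NULL))
#' superpose_rmsd(a, apply_transform(screw_transform(30, 5), a))$rmsd
#' @export
superpose_rmsd <- function(coords_a, coords_b) {
  a <- rbind(coords_a); b <- rbind(coords_b)
  if (!is.null(rownames(a)) && !is.null(rownames(b))) {
    common <- intersect(rownames(a), rownames(b))
    if (length(common) < 3)
      stop("fewer than 3 common labeled points between the two sets")
    a <- a[common, , drop = FALSE]
    b <- b[common, , drop = FALSE]
  } else if (nrow(a) != nrow(b)) {
    stop("unlabeled point sets must have equal numbers of rows")
  }
  if (nrow(a) < 3) stop("fewer than 3 points to superpose")
  k <- kabsch(a, b)
  list(rmsd = k$rmsd, transform = k$transform, n_used = nrow(a))
}
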
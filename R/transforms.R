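## Rigid-body transforms. All rotations are proper (det = +1); angles are
## degrees at the user interface and radians internally.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Rigid-body transform
#'
#' A proper rotation plus a translation, applied as `x -> R x + t`.
#'
#' @param rotation 3x3 orthonormal matrix with determinant +1.
#' @param translation numeric length-3 translation vector (Angstrom).
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  if (!all(dim(rotation) == c(3L, 3L)) || anyNA(rotation))
    stop("rotation must be a 3x3 numeric matrix")
  if (abs(det(rotation) - 1) > 1e-9)
    stop("rotation must be proper (det = +1 within 1e-9)")
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-8)
    stop("rotation must be orthonormal")
  translation <- as.numeric(translation)
  if (length(translation) != 3L || anyNA(translation))
    stop("translation must be a finite length-3 vector")
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("<rigid_transform>\n")
  cat("rotation:\n"); print(round(x$rotation, 6))
  cat("translation:", paste(round(x$translation, 6), collapse = " "), "\n")
  invisible(x)
}

#' Compose two rigid transforms
#'
#' `rt_compose(a, b)` is the transform "b then a": `x -> a(b(x))`.
#'
#' @param a,b `rigid_transform` objects.
#' @return A `rigid_transform`.
#' @export
rt_compose <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  as.numeric(a$rotation %*% b$translation) + a$translation)
}

#' Invert a rigid transform
#' @param rt a `rigid_transform`.
#' @return The inverse `rigid_transform`.
#' @export
rt_inverse <- function(rt) {
  rigid_transform(t(rt$rotation), -as.numeric(t(rt$rotation) %*% rt$translation))
}

#' Apply a rigid transform to coordinates
#'
#' @param rt a `rigid_transform`.
#' @param xyz numeric n x 3 matrix of coordinates (or a length-3 vector).
#' @return Transformed coordinates, same shape as the input matrix.
#' @export
rt_apply <- function(rt, xyz) {
  if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3L)
  sweep(xyz %*% t(rt$rotation), 2L, rt$translation, "+")
}

## Rotation about +z by theta degrees, right-hand rule (counterclockwise
## viewed from +z).
rot_z <- function(theta_deg) {
  th <- deg2rad(theta_deg)
  c_ <- cos(th); s_ <- sin(th)
  matrix(c(c_, s_, 0, -s_, c_, 0, 0, 0, 1), 3L, 3L)
}

#' Optimal superposition of two coordinate sets (Kabsch)
#'
#' Least-squares fit of `p` onto `q` (row-wise atom correspondence) via the
#' SVD of the covariance matrix. By default only proper rotations are
#' allowed; with `allow_reflection = TRUE` the unconstrained orthogonal fit
#' is returned, which diagnoses mirror-image (opposite-handed) pairs.
#'
#' @param p,q n x 3 coordinate matrices with matched rows.
#' @param allow_reflection allow an improper (det = -1) fit.
#' @return list with `rotation`, `translation`, `rmsd` (Angstrom) and
#'   `reflected` (logical; only possibly TRUE when reflections are allowed).
#' @export
kabsch_fit <- function(p, q, allow_reflection = FALSE) {
  p <- as.matrix(p); q <- as.matrix(q)
  stopifnot(ncol(p) == 3L, all(dim(p) == dim(q)), nrow(p) >= 3L)
  cp <- colMeans(p); cq <- colMeans(q)
  p0 <- sweep(p, 2L, cp); q0 <- sweep(q, 2L, cq)
  sv <- svd(crossprod(p0, q0))       # H = t(p0) %*% q0
  d <- det(sv$v %*% t(sv$u))
  reflected <- FALSE
  if (d < 0 && !allow_reflection) {
    s <- diag(c(1, 1, -1))
    rot <- sv$v %*% s %*% t(sv$u)
  } else {
    rot <- sv$v %*% t(sv$u)
    reflected <- d < 0
  }
  trans <- cq - as.numeric(rot %*% cp)
  fit <- sweep(p %*% t(rot), 2L, trans, "+")
  rmsd <- sqrt(mean(rowSums((fit - q)^2)))
  list(rotation = rot, translation = trans, rmsd = rmsd, reflected = reflected)
}
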
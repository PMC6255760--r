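## Filament construction from a monomer plus a screw symmetry, and the
## inverse problem: recovering (rise, twist) from a built filament.

#' Build a filament by screw propagation
#'
#' Subunit k (k = 0 .. n-1) is the monomer transformed by
#' `screw_operator(params, k)`; subunit 0 is the monomer itself. The
#' monomer centroid must lie off the +z filament axis so that propagation
#' produces a tube rather than a stack.
#'
#' @param monomer a [monomer_model()].
#' @param params a [helical_params()] object.
#' @param n number of subunits, >= 1.
#' @return A [filament_model()].
#' @export
build_filament <- function(monomer, params, n) {
  stopifnot(inherits(monomer, "monomer_model"), inherits(params, "helical_params"))
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("n must be an integer >= 1")
  xyz <- atom_xyz(monomer$atoms)
  cen <- colMeans(xyz)
  if (sqrt(sum(cen[1:2]^2)) < 1e-6)
    stop("monomer centroid lies on the filament axis; offset it radially first")
  subunits <- lapply(seq_len(n) - 1L, function(k) {
    tr <- screw_operator(params, k)
    a <- set_atom_xyz(monomer$atoms, rt_apply(tr, xyz))
    list(index = k, transform = tr, atoms = a)
  })
  filament_model(subunits, params = params, monomer = monomer)
}

#' Filament diameter
#'
#' Twice the 95th-percentile radial distance of heavy atoms from the
#' filament axis (+z). The percentile makes the estimate robust to a few
#' protruding side chains, mimicking a visual caliper measurement.
#'
#' @param filament a `filament_model`.
#' @return Diameter in Angstrom.
#' @export
filament_diameter <- function(filament) {
  stopifnot(inherits(filament, "filament_model"))
  atoms <- filament_atoms(filament)
  atoms <- atoms[atoms$is_heavy, , drop = FALSE]
  if (nrow(atoms) == 0L) stop("filament has no heavy atoms")
  r <- sqrt(atoms$x^2 + atoms$y^2)
  2 * as.numeric(stats::quantile(r, 0.95))
}

## Decompose the proper rotation of a rigid transform into (axis, angle);
## angle in degrees in [0, 180].
rotation_axis_angle <- function(R) {
  ct <- (sum(diag(R)) - 1) / 2
  ct <- min(1, max(-1, ct))
  theta <- acos(ct)
  if (theta < 1e-12) return(list(axis = c(0, 0, 1), angle = 0))
  if (pi - theta < 1e-6) {
    ## angle ~ 180: axis from the dominant column of R + I
    B <- R + diag(3)
    ax <- B[, which.max(colSums(B^2))]
    return(list(axis = ax / sqrt(sum(ax^2)), angle = rad2deg(theta)))
  }
  ax <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) /
    (2 * sin(theta))
  list(axis = ax / sqrt(sum(ax^2)), angle = rad2deg(theta))
}

#' Recover helical parameters from a filament
#'
#' Least-squares superposition (Kabsch) of each subunit onto its successor
#' yields the inter-subunit screw transform; the signed twist is the
#' rotation angle about the screw axis, oriented so the axial translation
#' (the rise) is positive. Estimates from all consecutive pairs are
#' averaged, which suppresses coordinate noise. Noise-free round trips are
#' exact to well below 1e-6.
#'
#' @param filament a `filament_model` with >= 2 subunits whose subunits are
#'   copies of a common monomer (same atom count/order per subunit).
#' @param congruence_tol maximum post-fit RMSD (Angstrom) before the input
#'   is rejected as not a filament of identical subunits.
#' @return A [helical_params()] object.
#' @export
recover_params_from_filament <- function(filament, congruence_tol = 1.5) {
  stopifnot(inherits(filament, "filament_model"))
  ns <- n_subunits(filament)
  if (ns < 2L) stop("need at least two subunits to recover helical parameters")
  coords <- lapply(filament$subunits, function(s) atom_xyz(s$atoms))
  nr <- vapply(coords, nrow, 0L)
  if (length(unique(nr)) != 1L)
    stop("not a filament: subunits have differing atom counts")
  rises <- twists <- numeric(ns - 1L)
  for (k in seq_len(ns - 1L)) {
    f <- kabsch_fit(coords[[k]], coords[[k + 1L]])
    if (f$rmsd > congruence_tol)
      stop(sprintf("not a filament: subunits %d and %d differ (RMSD %.3f A > %.3f A)",
                   k - 1L, k, f$rmsd, congruence_tol))
    aa <- rotation_axis_angle(f$rotation)
    axial <- sum(aa$axis * f$translation)
    if (axial < 0) {          # orient the screw axis so the rise is positive
      aa$axis <- -aa$axis
      aa$angle <- -aa$angle
      axial <- -axial
    }
    rises[k] <- axial
    twists[k] <- aa$angle
  }
  helical_params(mean(rises), wrap_angle(mean(twists)))
}

#' Signed handedness of a filament from its subunit centroids
#'
#' Accumulates the z-component of successive cross products of
#' axis-projected centroid offsets; its sign matches the sign of the twist
#' (negative = left-handed).
#'
#' @param filament a `filament_model` with >= 3 subunits.
#' @return +1 or -1.
#' @export
filament_handedness <- function(filament) {
  stopifnot(inherits(filament, "filament_model"))
  cen <- t(vapply(filament$subunits,
                  function(s) colMeans(atom_xyz(s$atoms)), numeric(3L)))
  if (nrow(cen) < 3L) stop("need at least three subunits to read handedness")
  v <- cen[, 1:2, drop = FALSE]          # radial components (axis = +z)
  cz <- 0
  for (k in seq_len(nrow(v) - 1L))
    cz <- cz + v[k, 1L] * v[k + 1L, 2L] - v[k, 2L] * v[k + 1L, 1L]
  if (cz == 0) stop("degenerate centroid geometry: handedness undefined")
  unname(sign(cz))
}
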
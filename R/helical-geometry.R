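## Screw-symmetry algebra for one-start C1 helical filaments.
##
## Convention: the filament axis is +z in a right-handed frame; a positive
## twist is a counterclockwise rotation per subunit viewed from +z, so a
## negative twist describes a left-handed filament.  The RIP2-CARD filament
## is left-handed, with defaults rise = 4.936 A and twist = -101.4 deg.

#' Helical symmetry parameters
#'
#' The screw symmetry of a one-start helical filament: the axial rise per
#' subunit and the signed azimuthal twist per subunit. A negative twist
#' denotes a left-handed filament.
#'
#' @param rise axial rise per subunit, Angstrom, > 0.
#' @param twist signed rotation per subunit, degrees, in (-180, 180], != 0.
#' @param point_group point-group symmetry; only "C1" is supported.
#' @return An object of class `helical_params`.
#' @examples
#' p <- helical_params(4.936, -101.4)
#' helical_pitch(p)
#' @export
helical_params <- function(rise, twist, point_group = "C1") {
  rise <- as.numeric(rise); twist <- as.numeric(twist)
  if (length(rise) != 1L || !is.finite(rise) || rise <= 0)
    stop("rise must be a single positive number (Angstrom)")
  if (length(twist) != 1L || !is.finite(twist) || twist == 0)
    stop("twist must be a single nonzero angle in degrees")
  if (twist <= -180 || twist > 180)
    stop("twist must lie in (-180, 180] degrees")
  if (!identical(point_group, "C1"))
    stop("only C1 point-group symmetry is supported")
  structure(list(rise = rise, twist = twist, point_group = "C1"),
            class = "helical_params")
}

#' @export
print.helical_params <- function(x, ...) {
  cat(sprintf("<helical_params> rise %.4f A, twist %+.4f deg (%s, %s-handed)\n",
              x$rise, x$twist, x$point_group,
              if (x$twist < 0) "left" else "right"))
  invisible(x)
}

#' Default RIP2-CARD filament symmetry
#'
#' The refined symmetry of the RIP2-CARD filament: rise 4.936 Angstrom,
#' twist -101.4 degrees (left-handed, C1). Nearby printed values
#' (101.36, 101.373) can be supplied explicitly to [helical_params()].
#'
#' @return A `helical_params` object.
#' @export
rip2_params <- function() helical_params(4.936, -101.4)

#' Screw operator for subunit k
#'
#' The rigid transform that places subunit `k` of a filament: rotation by
#' `k * twist` about +z composed with translation `(0, 0, k * rise)`.
#' Satisfies the group law `S(a) o S(b) = S(a + b)`.
#'
#' @param params a [helical_params()] object.
#' @param k integer subunit index (may be negative).
#' @return A [rigid_transform()].
#' @export
screw_operator <- function(params, k) {
  stopifnot(inherits(params, "helical_params"), length(k) == 1L, is.finite(k))
  rigid_transform(rot_z(k * params$twist), c(0, 0, k * params$rise))
}

#' Helical pitch
#'
#' Axial distance per full 360-degree turn: `(360 / |twist|) * rise`.
#'
#' @param params a [helical_params()] object.
#' @return Pitch in Angstrom.
#' @export
helical_pitch <- function(params) (360 / abs(params$twist)) * params$rise

#' Protrusion spacing on a 2D projection
#'
#' The distance between successive protrusion points visible on a filament
#' projection. For this lattice it equals two helical pitches:
#' `(720 / |twist|) * rise`.
#'
#' @param params a [helical_params()] object.
#' @return Spacing in Angstrom.
#' @examples
#' protrusion_spacing(helical_params(4.96, -101.36))  # 35.23
#' @export
protrusion_spacing <- function(params) (720 / abs(params$twist)) * params$rise

#' Subunits per helical turn
#' @param params a [helical_params()] object.
#' @return `360 / |twist|` (real, typically non-integer).
#' @export
subunits_per_turn <- function(params) 360 / abs(params$twist)

#' Number of complete subunits in an axial span
#'
#' How many subunits fit in `span` Angstrom of filament:
#' `floor(span / rise)`. A 60 A segment at rise 4.936 holds 12 subunits.
#'
#' @param span axial span in Angstrom, > 0.
#' @param params a [helical_params()] object.
#' @return Integer subunit count.
#' @export
subunit_count_in_span <- function(span, params) {
  if (!is.numeric(span) || length(span) != 1L || !is.finite(span) || span <= 0)
    stop("span must be a single positive length in Angstrom")
  as.integer(floor(span / params$rise))
}

#' Lattice geometry of the k-th neighbour shells
#'
#' For lattice offsets `dk = 1 .. max_offset`, the axial separation
#' `dz = dk * rise` and the azimuthal separation `dtheta = wrap(dk * twist)`
#' wrapped to (-180, 180]. For the RIP2 defaults the smallest |dtheta|
#' among dk = 1..6 occurs at dk = 4 (near-axial stacking).
#'
#' @param params a [helical_params()] object.
#' @param max_offset largest lattice offset, >= 1.
#' @return data.frame with columns `dk`, `dz`, `dtheta`.
#' @export
neighbor_geometry <- function(params, max_offset = 6L) {
  stopifnot(inherits(params, "helical_params"))
  max_offset <- as.integer(max_offset)
  if (is.na(max_offset) || max_offset < 1L) stop("max_offset must be >= 1")
  dk <- seq_len(max_offset)
  data.frame(dk = dk,
             dz = dk * params$rise,
             dtheta = wrap_angle(dk * params$twist))
}

## Wrap an angle in degrees to (-180, 180].
wrap_angle <- function(x) {
  w <- x - 360 * floor(x / 360)      # [0, 360)
  ifelse(w > 180, w - 360, w)
}

#' The two signed twist candidates from a projection
#'
#' Layer-line analysis of a single 2D projection fixes the twist magnitude
#' but not the hand: an in-plane mirrored filament produces an identical
#' amplitude spectrum. Both signed candidates are returned with a flag
#' recording that handedness must come from 3D density (for RIP2 the map
#' fixed the left hand, -101 deg).
#'
#' @param magnitude twist magnitude in degrees, in (0, 180].
#' @return list with `candidates` (numeric, one or two values), `resolved`
#'   (FALSE), and `note`.
#' @export
twist_sign_ambiguity <- function(magnitude) {
  magnitude <- as.numeric(magnitude)
  if (length(magnitude) != 1L || !is.finite(magnitude) ||
      magnitude <= 0 || magnitude > 180)
    stop("twist magnitude must lie in (0, 180] degrees")
  cands <- if (magnitude == 180) 180 else c(magnitude, -magnitude)
  list(candidates = cands,
       resolved = FALSE,
       note = paste("handedness is not determined by a single 2D projection;",
                    "a 3D density map is required to fix the sign"))
}
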
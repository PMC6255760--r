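## Forward simulation of filament projection images.
##
## The noise model is additive white Gaussian only; no contrast transfer
## function, dose or detector effects are simulated - the layer-line
## arithmetic this package reproduces does not need them.

#' Specification of a simulated micrograph
#'
#' @param pixel_size Angstrom per pixel (> 0); the study used 2.11 (negative
#'   stain) and 1.23 (cryo).
#' @param box image side in pixels, >= 64.
#' @param noise_sigma additive Gaussian noise, as a fraction of the peak
#'   noise-free signal (0 = noiseless; 0.5 corresponds to SNR 2).
#' @param blur_sigma width (Angstrom) of the isotropic Gaussian each heavy
#'   atom is splatted as; stands in for finite resolution.
#' @param seed integer seed for the noise field.
#' @return An object of class `micrograph_spec`.
#' @export
micrograph_spec <- function(pixel_size = 1.23, box = 512L, noise_sigma = 0,
                            blur_sigma = 1.5, seed = 1L) {
  if (!is.numeric(pixel_size) || pixel_size <= 0) stop("pixel_size must be > 0")
  box <- as.integer(box)
  if (is.na(box) || box < 64L) stop("box must be at least 64 pixels")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  if (blur_sigma <= 0) stop("blur_sigma must be > 0")
  structure(list(pixel_size = pixel_size, box = box,
                 noise_sigma = noise_sigma, blur_sigma = blur_sigma,
                 seed = as.integer(seed)),
            class = "micrograph_spec")
}

#' Projection image container
#'
#' @param pixels numeric matrix; the filament axis (z) runs along rows
#'   (first index), the transverse direction (y) along columns.
#' @param pixel_size Angstrom per pixel.
#' @param spec optional generating `micrograph_spec` (bookkeeping).
#' @return An object of class `projection_image`.
#' @export
projection_image <- function(pixels, pixel_size, spec = NULL) {
  stopifnot(is.matrix(pixels), pixel_size > 0)
  structure(list(pixels = pixels, pixel_size = pixel_size,
                 axis_orientation = "rows", spec = spec),
            class = "projection_image")
}

#' @export
print.projection_image <- function(x, ...) {
  cat(sprintf("<projection_image> %d x %d px at %.3f A/px (axis along rows)\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size))
  invisible(x)
}

#' Render a noisy 2D projection of a filament
#'
#' Projects along +x onto the (y, z) plane: each heavy atom becomes an
#' isotropic Gaussian of width `blur_sigma` at its (y, z) position; noise
#' is added with the spec's seed and the image is mean-subtracted. The
#' image is centred on the filament's axial mid-point. A filament longer
#' than `box * pixel_size` is truncated with a warning.
#'
#' @param filament a `filament_model` (axis = +z).
#' @param spec a [micrograph_spec()].
#' @return A [projection_image()].
#' @export
render_micrograph <- function(filament, spec = micrograph_spec()) {
  stopifnot(inherits(filament, "filament_model"),
            inherits(spec, "micrograph_spec"))
  atoms <- filament_atoms(filament)
  atoms <- atoms[atoms$is_heavy, , drop = FALSE]
  n <- spec$box
  ps <- spec$pixel_size
  extent <- n * ps
  zmid <- (min(atoms$z) + max(atoms$z)) / 2
  if ((max(atoms$z) - min(atoms$z)) > extent)
    warning("filament longer than the field of view; projection truncated")
  ## pixel centres: row i -> z = (i - (n+1)/2)*ps + zmid ; col j -> y = (j - (n+1)/2)*ps
  zpx <- (atoms$z - zmid) / ps + (n + 1) / 2
  ypx <- atoms$y / ps + (n + 1) / 2
  sig <- spec$blur_sigma / ps
  w <- max(2L, ceiling(4 * sig))
  img <- matrix(0, n, n)
  for (a in seq_along(zpx)) {
    i0 <- round(zpx[a]); j0 <- round(ypx[a])
    if (i0 + w < 1L || i0 - w > n || j0 + w < 1L || j0 - w > n) next
    ii <- max(1L, i0 - w):min(n, i0 + w)
    jj <- max(1L, j0 - w):min(n, j0 + w)
    gz <- exp(-(ii - zpx[a])^2 / (2 * sig^2))
    gy <- exp(-(jj - ypx[a])^2 / (2 * sig^2))
    img[ii, jj] <- img[ii, jj] + outer(gz, gy)
  }
  if (spec$noise_sigma > 0) {
    sd <- spec$noise_sigma * max(img)
    img <- img + with_seed(spec$seed,
                           matrix(stats::rnorm(n * n, sd = sd), n, n))
  }
  img <- img - mean(img)
  projection_image(img, ps, spec = spec)
}

## ---- MRC (mode 2) -----------------------------------------------------

#' Write a projection image as an MRC (mode 2) map
#'
#' Little-endian MRC2014 single-section float map, with the pixel size
#' recorded in the cell dimensions.
#'
#' @param image a `projection_image`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mrc <- function(image, path) {
  stopifnot(inherits(image, "projection_image"))
  px <- image$pixels
  nx <- ncol(px); ny <- nrow(px)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")
  wi(c(nx, ny, 1L, 2L))                    # nx ny nz mode
  wi(c(0L, 0L, 0L))                        # nxstart nystart nzstart
  wi(c(nx, ny, 1L))                        # mx my mz
  wf(c(nx, ny, 1) * image$pixel_size)      # cell a b c
  wf(c(90, 90, 90))                        # cell angles
  wi(c(1L, 2L, 3L))                        # mapc mapr maps
  wf(c(min(px), max(px), mean(px)))        # dmin dmax dmean
  wi(c(0L, 0L))                            # ispg nsymbt
  wi(rep(0L, 25L))                         # extra
  wf(c(0, 0, 0))                           # origin
  writeBin(charToRaw("MAP "), con)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)   # machine stamp (LE)
  wf(stats::sd(px))                        # rms
  wi(0L)                                   # nlabl
  writeBin(raw(800L), con)                 # labels
  writeBin(as.numeric(t(px)), con, size = 4L, endian = "little")
  invisible(path)
}

#' Read an MRC (mode 2) single-section map written by [write_mrc()]
#'
#' @param path input path.
#' @return A `projection_image`.
#' @export
read_mrc <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(n) readBin(con, "integer", n, size = 4L, endian = "little")
  rf <- function(n) readBin(con, "numeric", n, size = 4L, endian = "little")
  hd <- ri(4L)
  if (hd[4L] != 2L) stop("only MRC mode 2 (float) is supported")
  nx <- hd[1L]; ny <- hd[2L]; nz <- hd[3L]
  if (nz != 1L) stop("only single-section MRC maps are supported")
  ri(3L); mx <- ri(3L)
  cell <- rf(3L)
  pixel_size <- cell[1L] / mx[1L]
  seek(con, 1024L)
  vals <- rf(nx * ny)
  projection_image(matrix(vals, nrow = ny, ncol = nx, byrow = TRUE),
                   pixel_size)
}
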